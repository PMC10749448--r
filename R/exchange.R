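#' Committed region transitions with a transient filter
#'
#' Scans a per-water region time series sampled at constant `dt` and commits
#' a raw region change at time t only if the molecule does not re-enter the
#' pre-change region within `(t, t + threshold]`. A discarded excursion is
#' erased - the series is treated as if the molecule had stayed - and the
#' scan resumes at the re-entry point. The default 0.1 ps threshold screens
#' temporary recrossing fluctuations from genuine exchanges.
#'
#' @param regions Character vector of region labels, one per frame.
#' @param dt Frame spacing (ps).
#' @param threshold Transient-filter time (ps), at least `dt`.
#' @param t0 Time of the first sample (ps).
#' @return data.frame of committed transitions: `t_leave` (time of the first
#'   sample in the new region, ps), `from`, `to`.
#' @export
committed_transitions <- function(regions, dt, threshold = 0.1, t0 = 0) {
  stopifnot(is.character(regions), length(regions) >= 1L, dt > 0)
  if (threshold < dt - 1e-12) {
    stop("contract error: threshold must be at least dt", call. = FALSE)
  }
  times <- t0 + (seq_along(regions) - 1L) * dt
  n <- length(regions)
  cur <- regions[1]
  i <- 2L
  t_leave <- numeric(0); from <- character(0); to <- character(0)
  while (i <= n) {
    if (regions[i] == cur) { i <- i + 1L; next }
    t <- times[i]
    win <- which(times > t & times <= t + threshold + 1e-12)
    ret <- win[regions[win] == cur]
    if (length(ret)) {
      i <- ret[1]                       # excursion erased; resume at re-entry
    } else {
      t_leave <- c(t_leave, t)
      from <- c(from, cur)
      to <- c(to, regions[i])
      cur <- regions[i]
      i <- i + 1L
    }
  }
  data.frame(t_leave = t_leave, from = from, to = to)
}

# Directed category labels and their undirected Table-style columns.
category_column <- c("T-L" = "T-L", "L-T" = "L-T-init", "T-B" = "T-B",
                     "B-T" = "T-B", "B-L" = "L-B", "L-B" = "L-B-init",
                     "T-L-B" = "T-L-B", "B-L-T" = "T-L-B")

#' Categorize committed transitions into exchange events
#'
#' Parses a molecule's committed region path into exchange episodes anchored
#' at the endpoint regions (tight and bulk). Between two consecutive endpoint
#' settlements there is either no loose visit (a direct `T-B`/`B-T` event) or
#' exactly one: a loose excursion that returns to its starting endpoint is a
#' single event (`T-L` for tight-loose-tight, `B-L` for bulk-loose-bulk), and
#' one that crosses to the other endpoint is a through-the-loose-shell event
#' (`T-L-B` or `B-L-T`). A path that begins in the loose shell resolves its
#' first settlement as `L-T` or `L-B` (origin unknown). A committed departure whose
#' resolution is cut off by the end of the series is still one exchange event
#' of its shell; it is counted with the two-region category reached so far
#' and `resolved = FALSE`. Mirror-image categories are reported together in
#' the undirected columns `T-L`, `L-B`, `T-B`, `T-L-B` used by the
#' residence-time summary.
#'
#' @param transitions data.frame from [committed_transitions()], optionally
#'   with a `water_id` column (events are then computed per molecule).
#' @return data.frame of events: `water_id` (NA when absent), `t_leave`
#'   (commit time of the departure opening the episode, ps), `from_region`,
#'   `to_region`, `category` (directed), `column` (undirected Table-style
#'   category).
#' @export
categorize_events <- function(transitions) {
  stopifnot(is.data.frame(transitions),
            all(c("t_leave", "from", "to") %in% names(transitions)))
  ids <- if ("water_id" %in% names(transitions)) transitions$water_id
         else rep(NA_integer_, nrow(transitions))
  ev <- list()
  for (id in unique(ids)) {
    tr <- transitions[ids %in% id, , drop = FALSE]
    tr <- tr[order(tr$t_leave), , drop = FALSE]
    if (!nrow(tr)) next
    # region run path: p[1] is the starting region, p[k+1] after transition k
    p <- c(tr$from[1], tr$to)
    entry_t <- c(NA_real_, tr$t_leave)  # time the molecule entered run k
    settle <- which(p != "loose")
    if (!length(settle)) next
    if (settle[1] > 1L) {               # path begins in the loose shell
      s1 <- settle[1]
      cat_dir <- paste0("L-", if (p[s1] == "tight") "T" else "B")
      ev[[length(ev) + 1L]] <- data.frame(
        water_id = id, t_leave = entry_t[s1], from_region = "loose",
        to_region = p[s1], category = cat_dir, resolved = TRUE)
    }
    if (length(settle) > 1L) {
      for (k in seq_len(length(settle) - 1L)) {
        a <- settle[k]; b <- settle[k + 1L]
        ra <- if (p[a] == "tight") "T" else "B"
        rb <- if (p[b] == "tight") "T" else "B"
        if (b == a + 1L) {              # direct endpoint-to-endpoint
          cat_dir <- paste0(ra, "-", rb)
          ev[[length(ev) + 1L]] <- data.frame(
            water_id = id, t_leave = entry_t[b], from_region = p[a],
            to_region = p[b], category = cat_dir, resolved = TRUE)
        } else {                        # exactly one loose run between
          cat_dir <- if (ra == rb) paste0(ra, "-L")
                     else paste0(ra, "-L-", rb)
          ev[[length(ev) + 1L]] <- data.frame(
            water_id = id, t_leave = entry_t[a + 1L], from_region = p[a],
            to_region = "loose", category = cat_dir, resolved = TRUE)
        }
      }
    }
    s_last <- settle[length(settle)]
    if (s_last < length(p)) {           # departure cut off by end of series
      ra <- if (p[s_last] == "tight") "T" else "B"
      ev[[length(ev) + 1L]] <- data.frame(
        water_id = id, t_leave = entry_t[s_last + 1L],
        from_region = p[s_last], to_region = "loose",
        category = paste0(ra, "-L"), resolved = FALSE)
    }
  }
  if (!length(ev)) {
    out <- data.frame(water_id = integer(0), t_leave = numeric(0),
                      from_region = character(0), to_region = character(0),
                      category = character(0), resolved = logical(0),
                      column = character(0))
  } else {
    out <- do.call(rbind, ev)
    out$column <- unname(category_column[out$category])
  }
  out
}

#' Exchange events for a labeled trajectory
#'
#' Convenience wrapper: extracts each water's region series from shell
#' labels, applies the transient filter, and categorizes the committed
#' transitions.
#'
#' @param labels An `lp_shell_labels` from [classify_shells()].
#' @param threshold Transient-filter time (ps).
#' @return data.frame of events as in [categorize_events()].
#' @export
exchange_events <- function(labels, threshold = 0.1) {
  stopifnot(inherits(labels, "lp_shell_labels"))
  dt <- attr(labels, "dt")
  trans <- list()
  for (id in unique(labels$water_id)) {
    sub <- labels[labels$water_id == id, ]
    sub <- sub[order(sub$frame), ]
    tr <- committed_transitions(as.character(sub$region), dt = dt,
                                threshold = threshold, t0 = sub$time[1])
    if (nrow(tr)) {
      tr$water_id <- id
      trans[[length(trans) + 1L]] <- tr
    }
  }
  if (!length(trans)) {
    return(categorize_events(data.frame(t_leave = numeric(0),
                                        from = character(0),
                                        to = character(0))))
  }
  categorize_events(do.call(rbind, trans))
}

#' Event counts by undirected category
#'
#' @param events data.frame from [categorize_events()].
#' @return Named numeric vector with entries `T-L`, `L-B`, `T-B`, `T-L-B`
#'   (initial loose resolutions `L-T`/`L-B` are folded into `T-L` and `L-B`).
#' @export
event_counts <- function(events) {
  col <- events$column
  col[col == "L-T-init"] <- "T-L"
  col[col == "L-B-init"] <- "L-B"
  out <- c("T-L" = sum(col == "T-L"), "L-B" = sum(col == "L-B"),
           "T-B" = sum(col == "T-B"), "T-L-B" = sum(col == "T-L-B"))
  out
}

#' Mean residence times by the direct method
#'
#' Computes, per shell, the total number of exchange events, the mean
#' residence time `MRT = t_sim * n_bar / N_ex` and the normalized mean
#' residence time `NMRT = MRT / n_bar = t_sim / N_ex`. The tight shell's
#' events are `T-L + T-B + T-L-B`; the loose shell's are
#' `T-L + L-B + T-L-B`.
#'
#' @param counts Named vector of undirected event counts (`T-L`, `L-B`,
#'   `T-B`, `T-L-B`), e.g. from [event_counts()].
#' @param t_sim Production span (ps).
#' @param n_tight,n_loose Mean shell occupancies (n-bar); optional, `NA`
#'   leaves the MRTs `NA` while the NMRTs are still defined.
#' @return List of class `lp_exchange_summary` with `counts`, `n_ex`
#'   (per-shell totals), `mrt`, `nmrt` (ps), `n_bar`, `t_sim`.
#' @export
nmrt_from_counts <- function(counts, t_sim, n_tight = NA_real_,
                             n_loose = NA_real_) {
  need <- c("T-L", "L-B", "T-B", "T-L-B")
  stopifnot(all(need %in% names(counts)), t_sim > 0)
  counts <- counts[need]
  n_ex <- c(tight = unname(counts["T-L"] + counts["T-B"] + counts["T-L-B"]),
            loose = unname(counts["T-L"] + counts["L-B"] + counts["T-L-B"]))
  if (any(n_ex == 0)) {
    stop("undefined-NMRT error: a shell has zero exchange events", call. = FALSE)
  }
  n_bar <- c(tight = unname(n_tight), loose = unname(n_loose))
  nmrt <- t_sim / n_ex
  mrt <- n_bar * nmrt
  structure(list(counts = counts, n_ex = n_ex, mrt = mrt, nmrt = nmrt,
                 n_bar = n_bar, t_sim = t_sim),
            class = "lp_exchange_summary")
}

#' @export
print.lp_exchange_summary <- function(x, ...) {
  cat("Exchange summary (direct method)\n")
  cat(sprintf("  events: T-L = %g, L-B = %g, T-B = %g, T-L-B = %g\n",
              x$counts["T-L"], x$counts["L-B"], x$counts["T-B"],
              x$counts["T-L-B"]))
  cat(sprintf("  t_sim = %g ps; N_ex tight = %g, loose = %g\n",
              x$t_sim, x$n_ex["tight"], x$n_ex["loose"]))
  cat(sprintf("  NMRT tight = %.3f ps, loose = %.3f ps\n",
              x$nmrt["tight"], x$nmrt["loose"]))
  if (!any(is.na(x$mrt))) {
    cat(sprintf("  MRT  tight = %.3f ps, loose = %.3f ps (n-bar %.2f / %.2f)\n",
                x$mrt["tight"], x$mrt["loose"], x$n_bar["tight"],
                x$n_bar["loose"]))
  }
  invisible(x)
}

#' Full exchange analysis of a labeled trajectory
#'
#' Chains [exchange_events()], [event_counts()], [shell_occupancy()] and
#' [nmrt_from_counts()].
#'
#' @param labels An `lp_shell_labels`.
#' @param threshold Transient-filter time (ps).
#' @return List with `events` and `summary` (an `lp_exchange_summary`).
#' @export
exchange_analysis <- function(labels, threshold = 0.1) {
  ev <- exchange_events(labels, threshold = threshold)
  occ <- shell_occupancy(labels)
  list(events = ev,
       summary = nmrt_from_counts(event_counts(ev), t_sim = attr(labels, "t_sim"),
                                  n_tight = occ["tight"], n_loose = occ["loose"]))
}
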