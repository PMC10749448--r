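#' Ion-water radial distribution function
#'
#' Histogram of minimum-image ion-partner distances, normalized per frame by
#' the exact spherical-shell volume of each bin and by the mean partner number
#' density of the whole box. The same whole-box normalization is used for
#' masked subsets, so the g(r) of a subset and of its complement sum bin-wise
#' to the total curve.
#'
#' @param traj An [lp_trajectory()].
#' @param pair_kind `"XO"` (ion-oxygen) or `"XH"` (ion-hydrogen; both
#'   hydrogens of every water are counted independently).
#' @param bin_width Bin width (Å).
#' @param r_max Histogram range (Å); must not exceed `box_edge/2`. Defaults to
#'   `box_edge/2`.
#' @param mask Optional logical n_frames x n_waters matrix (or a function of
#'   frame index returning a logical vector) selecting which waters
#'   contribute in each frame; both hydrogens of a water share its mask value.
#' @return An object of class `lp_rdf` with fields `r_centers`, `g`,
#'   `bin_width`, `pair_kind`, `n_frames`, `mean_density` and raw `counts`.
#' @export
compute_rdf <- function(traj, pair_kind = c("XO", "XH"), bin_width = 0.02,
                        r_max = NULL, mask = NULL) {
  pair_kind <- match.arg(pair_kind)
  stopifnot(inherits(traj, "lp_trajectory"), bin_width > 0)
  box <- traj$box_edge
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-12) {
    stop("contract error: r_max must not exceed box_edge/2", call. = FALSE)
  }
  nb <- floor(r_max / bin_width + 1e-9)
  edges <- (0:nb) * bin_width
  counts <- numeric(nb)
  nf <- n_frames(traj)
  nw <- n_waters(traj$frames[[1]])
  per_water <- if (pair_kind == "XO") 1L else 2L
  for (k in seq_len(nf)) {
    f <- traj$frames[[k]]
    keep <- if (is.null(mask)) rep(TRUE, n_waters(f))
            else if (is.function(mask)) mask(k) else mask[k, ]
    if (pair_kind == "XO") {
      pos <- f$o_xyz[keep, , drop = FALSE]
    } else {
      pos <- rbind(f$h1_xyz[keep, , drop = FALSE],
                   f$h2_xyz[keep, , drop = FALSE])
    }
    if (!nrow(pos)) next
    d <- row_norms(minimum_image(sweep(pos, 2, f$ion_xyz), box))
    d <- d[d < r_max]
    if (length(d)) {
      idx <- pmin(nb, floor(d / bin_width) + 1L)
      tb <- tabulate(idx, nbins = nb)
      counts <- counts + tb
    }
  }
  rho <- per_water * nw / box^3        # mean density of ALL partners in the box
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (nf * shell_vol * rho)
  structure(list(r_centers = edges[-1] - bin_width / 2, g = g,
                 bin_width = bin_width, pair_kind = pair_kind,
                 n_frames = nf, mean_density = rho, counts = counts),
            class = "lp_rdf")
}

#' @export
print.lp_rdf <- function(x, ...) {
  cat(sprintf("lp_rdf (%s): %d bins of %g Ang over %d frames, rho = %.5f / Ang^3\n",
              x$pair_kind, length(x$g), x$bin_width, x$n_frames, x$mean_density))
  invisible(x)
}

# Centered moving average, partial windows at the edges.
smooth_ma <- function(y, width = 5L) {
  h <- width %/% 2L
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(y[lo:hi])
  }
  out
}

#' First minimum of a radial distribution function
#'
#' Abscissa of the minimum of a 5-bin moving-average smoothed copy of the
#' curve inside a search window; ties resolve to the smallest r. The raw-bin
#' minimum position is attached as attribute `"raw"`. A window in which the
#' smoothed curve is monotone (minimum at a window edge) raises a
#' no-minimum error.
#'
#' @param rdf An `lp_rdf`.
#' @param search_window Length-2 interval (Å) to search in.
#' @return First-minimum position (Å) with attribute `"raw"`.
#' @export
first_minimum <- function(rdf, search_window) {
  stopifnot(inherits(rdf, "lp_rdf"), length(search_window) == 2L)
  sm <- smooth_ma(rdf$g, 5L)
  in_win <- rdf$r_centers >= search_window[1] & rdf$r_centers <= search_window[2]
  if (sum(in_win) < 3L) {
    stop("no-minimum error: search window covers fewer than 3 bins", call. = FALSE)
  }
  idx <- which(in_win)
  i_min <- idx[which.min(sm[idx])]          # which.min: first (smallest r) tie
  if (i_min == idx[1] || i_min == idx[length(idx)]) {
    stop("no-minimum error: curve is monotone within the search window",
         call. = FALSE)
  }
  out <- rdf$r_centers[i_min]
  j <- idx[which.min(rdf$g[idx])]
  attr(out, "raw") <- rdf$r_centers[j]
  out
}

#' Mean first-shell coordination number
#'
#' Time average of the per-frame count of water oxygens with minimum-image
#' ion-oxygen distance below `r_cut` (`method = "count"`), or the integral
#' `4 pi rho int g(r) r^2 dr` of the ion-oxygen g(r) up to `r_cut`
#' (`method = "integrate"`). The two agree to within one bin's
#' discretization.
#'
#' @param traj An [lp_trajectory()].
#' @param r_cut Cutoff distance (Å), at most `box_edge/2`.
#' @param method `"count"` or `"integrate"`.
#' @param bin_width Bin width used when integrating.
#' @return Mean coordination number.
#' @export
coordination_number <- function(traj, r_cut, method = c("count", "integrate"),
                                bin_width = 0.02) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "lp_trajectory"), r_cut > 0)
  if (r_cut > traj$box_edge / 2 + 1e-12) {
    stop("contract error: r_cut must not exceed box_edge/2", call. = FALSE)
  }
  if (method == "count") {
    mean(vapply(traj$frames, function(f) sum(frame_r_xo(f) < r_cut), numeric(1)))
  } else {
    rdf <- compute_rdf(traj, "XO", bin_width = bin_width)
    edges <- c(rdf$r_centers - bin_width / 2, max(rdf$r_centers) + bin_width / 2)
    shell_vol <- 4 / 3 * pi * diff(edges^3)
    keep <- rdf$r_centers < r_cut
    sum(rdf$g[keep] * shell_vol[keep]) * rdf$mean_density
  }
}
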