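#' The eta descriptor: angle-weighted lone-pair-hydrogen distance
#'
#' `eta = r_lp_h * sec(alpha/2) * sec(beta/2)`, a length-valued measure of
#' hydrogen-bond strength between an ion lone pair and a water hydrogen.
#' `alpha` is the angle at the ion between the ion->lone-pair direction and
#' the ion->hydrogen direction; `beta` is the angle at the hydrogen between
#' the O->H bond direction and the H->lone-pair direction. The ideal linear
#' hydrogen bond has `alpha = beta = 0`, where both angular weights equal 1
#' and eta reduces to the lone-pair-hydrogen distance; eta grows strictly
#' with `r_lp_h` at fixed angles and with either angle away from linearity,
#' so lower eta means stronger interaction.
#'
#' @param r_lp_h Lone-pair-hydrogen distance (Å), `> 0`.
#' @param alpha,beta Angles in degrees, each in `[0, 180)`. Values outside
#'   that range (including exactly 180, where the weight diverges) raise a
#'   domain error.
#' @return eta (Å). Vectorized over its arguments.
#' @export
eta_value <- function(r_lp_h, alpha, beta) {
  if (any(r_lp_h <= 0)) {
    stop("domain error: r_lp_h must be positive", call. = FALSE)
  }
  if (any(alpha < 0 | alpha >= 180 | beta < 0 | beta >= 180)) {
    stop("domain error: alpha and beta must lie in [0, 180)", call. = FALSE)
  }
  r_lp_h / (cos(alpha * pi / 360) * cos(beta * pi / 360))
}

# Same algebra on precomputed cosines of the full angles; angles of exactly
# 180 degrees give +Inf instead of an error (used by the vectorized fast
# path, where a diverging combination simply never becomes the minimum).
eta_from_cos <- function(r_lp_h, cos_a, cos_b) {
  wa <- sqrt(pmax((1 + cos_a) / 2, 0))   # cos(alpha/2)
  wb <- sqrt(pmax((1 + cos_b) / 2, 0))
  ifelse(wa * wb > 0, r_lp_h / (wa * wb), Inf)
}

#' Geometry of one (lone pair, hydrogen) ion-water contact
#'
#' @param frame An [lp_frame()].
#' @param water_id Water identifier present in the frame.
#' @param lp_index Lone-pair index, 1-4.
#' @param h_index Hydrogen index, 1-2.
#' @return A list of class `lp_pair_geometry` with `water_id`, `lp_index`,
#'   `h_index`, `r_lp_h`, `alpha`, `beta`, `eta`, `r_xo`, `r_xh` (distances in
#'   Å, angles in degrees).
#' @export
pair_geometry <- function(frame, water_id, lp_index, h_index) {
  stopifnot(inherits(frame, "lp_frame"),
            lp_index %in% 1:4, h_index %in% 1:2)
  w <- match(water_id, frame$water_ids)
  if (is.na(w)) stop("water_id not present in frame", call. = FALSE)
  box <- frame$box_edge
  h <- if (h_index == 1L) frame$h1_xyz[w, ] else frame$h2_xyz[w, ]
  o <- frame$o_xyz[w, ]
  lp <- frame$lp_xyz[lp_index, ]
  ion <- frame$ion_xyz

  v_ion_lp <- minimum_image(lp - ion, box)
  v_ion_h <- minimum_image(h - ion, box)
  v_ion_o <- minimum_image(o - ion, box)
  v_lp_h <- minimum_image(h - lp, box)
  v_o_h <- minimum_image(h - o, box)

  r_lp_h <- sqrt(sum(v_lp_h^2))
  if (r_lp_h == 0) stop("invalid geometry: coincident lone pair and hydrogen",
                        call. = FALSE)
  alpha <- angle_between(v_ion_lp, v_ion_h)
  beta <- angle_between(v_o_h, -v_lp_h)
  structure(list(water_id = water_id, lp_index = lp_index, h_index = h_index,
                 r_lp_h = r_lp_h, alpha = alpha, beta = beta,
                 eta = eta_value(r_lp_h, alpha, beta),
                 r_xo = sqrt(sum(v_ion_o^2)), r_xh = sqrt(sum(v_ion_h^2))),
            class = "lp_pair_geometry")
}

# Vectorized per-frame eta computation: for every water, evaluate all
# 4 x 2 (lone pair, hydrogen) combinations and keep the minimizing one
# (ties to the lexicographically smallest (lp_index, h_index)).
# Returns a data.frame: water_id, eta, lp_index, h_index, r_xo.
frame_eta <- function(frame) {
  box <- frame$box_edge
  ion <- frame$ion_xyz
  n <- n_waters(frame)
  H <- rbind(frame$h1_xyz, frame$h2_xyz)          # rows 1..n = H1, n+1..2n = H2
  O2 <- rbind(frame$o_xyz, frame$o_xyz)
  hrel <- minimum_image(sweep(H, 2, ion), box)
  lprel <- minimum_image(sweep(frame$lp_xyz, 2, ion), box)
  orel <- minimum_image(sweep(frame$o_xyz, 2, ion), box)
  r_xh <- row_norms(hrel)
  r_xo <- row_norms(orel)
  hu <- hrel / r_xh
  lpu <- lprel / row_norms(lprel)
  ohrel <- minimum_image(H - O2, box)
  ohu <- ohrel / row_norms(ohrel)

  cos_a <- lpu %*% t(hu)                           # 4 x 2n
  r_lp_h <- matrix(NA_real_, 4, 2 * n)
  cos_b <- matrix(NA_real_, 4, 2 * n)
  for (l in 1:4) {
    d <- minimum_image(sweep(H, 2, frame$lp_xyz[l, ]), box)  # LP -> H
    rl <- row_norms(d)
    r_lp_h[l, ] <- rl
    cos_b[l, ] <- rowSums(ohu * (-d)) / rl         # angle(O->H, H->LP)
  }
  cos_a <- pmin(pmax(cos_a, -1), 1)
  cos_b <- pmin(pmax(cos_b, -1), 1)
  eta <- eta_from_cos(r_lp_h, cos_a, cos_b)

  # combo index in lexicographic (lp, h) order: row c = (lp-1)*2 + h
  eta8 <- matrix(NA_real_, 8, n)
  for (l in 1:4) {
    eta8[2 * l - 1, ] <- eta[l, 1:n]
    eta8[2 * l, ] <- eta[l, n + 1:n]
  }
  best <- apply(eta8, 2, which.min)
  data.frame(water_id = frame$water_ids,
             eta = eta8[cbind(best, seq_len(n))],
             lp_index = (best - 1L) %/% 2L + 1L,
             h_index = (best - 1L) %% 2L + 1L,
             r_xo = r_xo)
}

#' Ion-water eta descriptor for one water
#'
#' Evaluates all 8 (lone pair, hydrogen) combinations and returns the
#' [pair_geometry()] of the minimizing one, i.e. the strongest lone-pair
#' contact; ties resolve to the lexicographically smallest
#' `(lp_index, h_index)`.
#'
#' @param frame An [lp_frame()].
#' @param water_id Water identifier present in the frame.
#' @return An `lp_pair_geometry` for the minimizing combination.
#' @export
eta_ion_water <- function(frame, water_id) {
  best <- NULL
  for (l in 1:4) {
    for (h in 1:2) {
      pg <- pair_geometry(frame, water_id, l, h)
      if (is.null(best) || pg$eta < best$eta) best <- pg
    }
  }
  best
}

#' Per-pair eta table for a whole trajectory
#'
#' One row per (frame, water): the minimized ion-water eta, the realizing
#' lone pair and hydrogen, and the ion-oxygen distance.
#'
#' @param traj An [lp_trajectory()].
#' @return data.frame with columns `frame` (1-based), `time`, `water_id`,
#'   `eta`, `lp_index`, `h_index`, `r_xo`.
#' @export
eta_table <- function(traj) {
  stopifnot(inherits(traj, "lp_trajectory"))
  out <- vector("list", n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    fe <- frame_eta(traj$frames[[k]])
    fe$frame <- k
    fe$time <- traj$frames[[k]]$time
    out[[k]] <- fe
  }
  do.call(rbind, out)[, c("frame", "time", "water_id", "eta",
                          "lp_index", "h_index", "r_xo")]
}

#' Construct an eta distribution object
#'
#' @param eta_centers Bin centers (Å), uniformly spaced.
#' @param p Normalized density values (`sum(p) * bin_width = 1` for nonempty
#'   selections).
#' @param selection Selection tag (`"all"`, `"rank14"`, `"rank57"`,
#'   `"custom"`).
#' @param n_samples Number of samples binned.
#' @return An object of class `lp_eta_distribution`.
#' @export
eta_distribution_obj <- function(eta_centers, p, selection = "custom",
                                 n_samples = NA_integer_) {
  stopifnot(length(eta_centers) == length(p), all(p >= 0))
  structure(list(eta_centers = eta_centers, p = p,
                 bin_width = if (length(eta_centers) > 1)
                   eta_centers[2] - eta_centers[1] else NA_real_,
                 selection = selection, n_samples = n_samples),
            class = "lp_eta_distribution")
}

#' Normalized eta distribution P(eta)
#'
#' Histogram of the per-pair minimized eta over frames x selected waters,
#' normalized to unit integral. Ranks are computed per frame by ascending
#' ion-oxygen distance.
#'
#' @param x An [lp_trajectory()] or a precomputed [eta_table()].
#' @param selection `"all"`, `"rank14"` (four nearest waters), `"rank57"`
#'   (5th-7th nearest), or a logical vector along the rows of the eta table
#'   (custom mask).
#' @param bin_width Bin width (Å).
#' @param r_range Length-2 histogram range (Å); defaults to `(0, max eta)`
#'   of the full table rounded up to a bin edge. Pass a common range when two
#'   distributions must share a grid.
#' @return An `lp_eta_distribution`.
#' @export
eta_distribution <- function(x, selection = "all", bin_width = 0.02,
                             r_range = NULL) {
  tab <- if (inherits(x, "lp_trajectory")) eta_table(x) else x
  stopifnot(is.data.frame(tab), all(c("frame", "eta", "r_xo") %in% names(tab)))
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(tab))
    keep <- selection
    tag <- "custom"
  } else {
    tag <- match.arg(selection, c("all", "rank14", "rank57"))
    if (tag == "all") {
      keep <- rep(TRUE, nrow(tab))
    } else {
      rk <- stats::ave(tab$r_xo, tab$frame,
                       FUN = function(v) rank(v, ties.method = "first"))
      keep <- if (tag == "rank14") rk <= 4 else rk >= 5 & rk <= 7
    }
  }
  sel <- tab$eta[keep]
  sel <- sel[is.finite(sel)]
  if (!length(sel)) stop("contract error: empty selection", call. = FALSE)
  if (is.null(r_range)) r_range <- c(0, ceiling(max(sel) / bin_width) * bin_width)
  nb <- ceiling((r_range[2] - r_range[1]) / bin_width - 1e-9)
  idx <- floor((sel - r_range[1]) / bin_width) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  cnt <- tabulate(idx, nbins = nb)
  p <- cnt / (length(sel) * bin_width)
  eta_distribution_obj(r_range[1] + (seq_len(nb) - 0.5) * bin_width, p,
                       selection = tag, n_samples = length(sel))
}

#' Eta cutoff from the intersection of two rank distributions
#'
#' Smallest eta at which the (5-bin smoothed) difference between the
#' rank-1-4 and rank-5-7 distributions changes sign from positive to
#' negative, linearly interpolated between the bracketing bin centers. This
#' is the cutoff separating the tight from the loose first shell.
#'
#' @param d14,d57 `lp_eta_distribution` objects on a common bin grid.
#' @return The crossing eta (Å).
#' @export
eta_cutoff_from_intersection <- function(d14, d57) {
  stopifnot(inherits(d14, "lp_eta_distribution"),
            inherits(d57, "lp_eta_distribution"))
  if (length(d14$eta_centers) != length(d57$eta_centers) ||
      any(abs(d14$eta_centers - d57$eta_centers) > 1e-9)) {
    stop("contract error: distributions must share a common bin grid",
         call. = FALSE)
  }
  both <- d14$p > 0 | d57$p > 0
  if (!any(d14$p > 0) || !any(d57$p > 0)) {
    stop("no-intersection error: a distribution is empty", call. = FALSE)
  }
  s14 <- smooth_ma(d14$p, 5L)
  s57 <- smooth_ma(d57$p, 5L)
  diffc <- s14 - s57
  idx <- range(which(both))
  for (i in idx[1]:(idx[2] - 1L)) {
    if (diffc[i] > 0 && diffc[i + 1L] < 0) {
      x1 <- d14$eta_centers[i]; x2 <- d14$eta_centers[i + 1L]
      d1 <- diffc[i]; d2 <- diffc[i + 1L]
      return(x1 + (x2 - x1) * d1 / (d1 - d2))
    }
  }
  stop("no-intersection error: no positive-to-negative crossing found",
       call. = FALSE)
}

#' Peak position of an eta distribution
#'
#' Abscissa of the global maximum after 5-bin moving-average smoothing.
#' Smoothing plateaus (e.g. an isolated single-bin spike smeared over the
#' window) are resolved by the raw curve, and remaining ties go to the
#' smallest eta.
#'
#' @param dist An `lp_eta_distribution`.
#' @return Peak eta (Å).
#' @export
eta_peak <- function(dist) {
  stopifnot(inherits(dist, "lp_eta_distribution"))
  if (!length(dist$p)) stop("contract error: empty distribution", call. = FALSE)
  sm <- smooth_ma(dist$p, 5L)
  cand <- which(sm >= max(sm) - 1e-12)
  cand <- cand[dist$p[cand] >= max(dist$p[cand]) - 1e-12]
  dist$eta_centers[cand[1]]
}

#' Rank-distribution eta cutoff for a trajectory
#'
#' Convenience wrapper: builds the rank-1-4 and rank-5-7 distributions on a
#' shared grid and returns their intersection cutoff together with both
#' distributions.
#'
#' @param traj An [lp_trajectory()] or an [eta_table()].
#' @param bin_width Bin width (Å).
#' @return List with `eta_cut`, `d14`, `d57`.
#' @export
eta_rank_cutoff <- function(traj, bin_width = 0.02) {
  tab <- if (inherits(traj, "lp_trajectory")) eta_table(traj) else traj
  rmax <- ceiling(max(tab$eta[is.finite(tab$eta)]) / bin_width) * bin_width
  d14 <- eta_distribution(tab, "rank14", bin_width, r_range = c(0, rmax))
  d57 <- eta_distribution(tab, "rank57", bin_width, r_range = c(0, rmax))
  list(eta_cut = eta_cutoff_from_intersection(d14, d57), d14 = d14, d57 = d57)
}
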