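#' Shell cutoffs
#'
#' Pair of cutoffs defining the shell decomposition: the conventional
#' first-shell distance cutoff `r_cut` (first minimum of the ion-oxygen
#' g(r)) and the eta cutoff `eta_cut` separating tight from loose waters.
#'
#' @param r_cut Distance cutoff (Å), `> 0`.
#' @param eta_cut Eta cutoff (Å), `> 0`.
#' @return A list of class `lp_shell_cutoffs`.
#' @export
shell_cutoffs <- function(r_cut, eta_cut) {
  if (!(r_cut > 0 && eta_cut > 0)) {
    stop("cutoffs must be positive", call. = FALSE)
  }
  structure(list(r_cut = r_cut, eta_cut = eta_cut), class = "lp_shell_cutoffs")
}

#' Classify waters into tight, loose and bulk shells
#'
#' Per frame and water: `tight` iff `eta < eta_cut` (note this does not
#' require the water inside `r_cut`: a farther molecule with a strong
#' lone-pair contact still belongs to the tight shell); otherwise `loose`
#' iff `r_xo < r_cut`, else `bulk`. Both comparisons are strict, so boundary
#' values fall in the outer region. Waters inside `r_cut` are additionally
#' flagged as misoriented when both hydrogens point away from the ion (angle
#' at the oxygen between O->H and O->ion above 90 degrees for both); such
#' waters keep their region label.
#'
#' @param traj An [lp_trajectory()].
#' @param cutoffs A [shell_cutoffs()], or `eta_cut` when `r_cut` is given
#'   separately.
#' @param r_cut Optional distance cutoff (Å) if `cutoffs` is a bare eta
#'   cutoff.
#' @return data.frame of class `lp_shell_labels`: `frame`, `time`,
#'   `water_id`, `region`, `eta`, `r_xo`, `misoriented`, with attributes
#'   `cutoffs`, `dt`, `t_sim`, `n_waters`.
#' @export
classify_shells <- function(traj, cutoffs, r_cut = NULL) {
  stopifnot(inherits(traj, "lp_trajectory"))
  if (!inherits(cutoffs, "lp_shell_cutoffs")) {
    cutoffs <- shell_cutoffs(r_cut = r_cut, eta_cut = cutoffs)
  }
  out <- vector("list", n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    fe <- frame_eta(f)
    region <- ifelse(fe$eta < cutoffs$eta_cut, "tight",
                     ifelse(fe$r_xo < cutoffs$r_cut, "loose", "bulk"))
    mis <- rep(NA, n_waters(f))
    inside <- fe$r_xo < cutoffs$r_cut
    if (any(inside)) {
      mis[inside] <- misoriented_frame(f)[inside]
    }
    out[[k]] <- data.frame(frame = k, time = f$time, water_id = fe$water_id,
                           region = region, eta = fe$eta, r_xo = fe$r_xo,
                           misoriented = mis)
  }
  labels <- do.call(rbind, out)
  attr(labels, "cutoffs") <- cutoffs
  attr(labels, "dt") <- traj$dt
  attr(labels, "t_sim") <- traj$t_sim
  attr(labels, "n_waters") <- n_waters(traj$frames[[1]])
  class(labels) <- c("lp_shell_labels", "data.frame")
  labels
}

# Per-frame misorientation test for every water: TRUE iff both O->H vectors
# make an angle above 90 degrees with O->ion.
misoriented_frame <- function(frame) {
  box <- frame$box_edge
  o2ion <- minimum_image(sweep(-frame$o_xyz, 2, frame$ion_xyz, `+`), box)
  oh1 <- minimum_image(frame$h1_xyz - frame$o_xyz, box)
  oh2 <- minimum_image(frame$h2_xyz - frame$o_xyz, box)
  rowSums(oh1 * o2ion) < 0 & rowSums(oh2 * o2ion) < 0
}

#' Is a water misoriented?
#'
#' TRUE iff both hydrogens lie in the hemisphere away from the ion: the angle
#' at the oxygen between each O->H bond and the O->ion direction exceeds 90
#' degrees. Such molecules sit inside the conventional first shell without
#' the orientation required to solvate the anion.
#'
#' @param frame An [lp_frame()].
#' @param water_id Water identifier.
#' @param r_cut Conventional first-shell cutoff (Å); the water must lie
#'   inside it.
#' @return Logical flag.
#' @export
flag_misoriented <- function(frame, water_id, r_cut) {
  w <- match(water_id, frame$water_ids)
  if (is.na(w)) stop("water_id not present in frame", call. = FALSE)
  if (frame_r_xo(frame)[w] >= r_cut) {
    stop("water lies outside r_cut; misorientation is defined inside the first shell",
         call. = FALSE)
  }
  misoriented_frame(frame)[w]
}

#' Instantaneous coordination-number distribution of a region
#'
#' Normalized histogram of the per-frame occupancy counts of a shell.
#'
#' @param labels An `lp_shell_labels` from [classify_shells()].
#' @param region `"tight"`, `"loose"` or `"bulk"`.
#' @return data.frame of class `lp_cn_distribution`: `n` (integer
#'   coordination number, from 0 to the observed maximum) and `p`
#'   (probability; sums to 1).
#' @export
cn_distribution <- function(labels, region = "tight") {
  stopifnot(inherits(labels, "lp_shell_labels"), nrow(labels) > 0)
  region <- match.arg(region, c("tight", "loose", "bulk"))
  per_frame <- tapply(labels$region == region, labels$frame, sum)
  mx <- max(per_frame)
  cnt <- tabulate(per_frame + 1L, nbins = mx + 1L)
  out <- data.frame(n = 0:mx, p = cnt / sum(cnt))
  class(out) <- c("lp_cn_distribution", "data.frame")
  out
}

#' Modal coordination number
#'
#' @param cnd An `lp_cn_distribution`.
#' @return The occupancy with the highest probability (smallest on ties).
#' @export
cn_mode <- function(cnd) {
  stopifnot(inherits(cnd, "lp_cn_distribution"))
  cnd$n[which.max(cnd$p)]
}

#' Mean region occupancies
#'
#' Time-averaged number of waters in each region; the n-bar entering the
#' residence-time normalization.
#'
#' @param labels An `lp_shell_labels`.
#' @return Named numeric vector with entries `tight`, `loose`, `bulk`.
#' @export
shell_occupancy <- function(labels) {
  stopifnot(inherits(labels, "lp_shell_labels"))
  nf <- length(unique(labels$frame))
  vapply(c(tight = "tight", loose = "loose", bulk = "bulk"),
         function(r) sum(labels$region == r) / nf, numeric(1))
}

#' Decompose the ion-oxygen g(r) by shell
#'
#' Computes the ion-oxygen g(r) restricted to tight-shell waters and to
#' its complement (loose shell + bulk), both sharing the total curve's
#' whole-box normalization so the two components sum bin-wise to the total
#' g(r).
#'
#' @param traj An [lp_trajectory()].
#' @param labels An `lp_shell_labels` aligned with `traj`.
#' @param bin_width Bin width (Å).
#' @param r_max Histogram range (Å).
#' @return List with `tight`, `loose_bulk` and `total` (`lp_rdf` objects).
#' @export
decomposed_rdf <- function(traj, labels, bin_width = 0.02, r_max = NULL) {
  stopifnot(inherits(traj, "lp_trajectory"), inherits(labels, "lp_shell_labels"))
  nf <- n_frames(traj)
  nw <- n_waters(traj$frames[[1]])
  if (nrow(labels) != nf * nw) {
    stop("labels are not aligned with the trajectory", call. = FALSE)
  }
  tight <- matrix(labels$region == "tight", nf, nw, byrow = TRUE)
  list(tight = compute_rdf(traj, "XO", bin_width, r_max, mask = tight),
       loose_bulk = compute_rdf(traj, "XO", bin_width, r_max, mask = !tight),
       total = compute_rdf(traj, "XO", bin_width, r_max))
}
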