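#' Minimum-image convention for a cubic periodic cell
#'
#' Maps each Cartesian component of one or more displacement vectors into
#' `[-box_edge/2, box_edge/2)`, i.e. replaces the vector by its shortest
#' periodic image. All interparticle vectors in the package pass through this
#' function, so analyses are independent of the wrapping convention of the
#' input coordinates.
#'
#' @param v Numeric vector of length 3, or an n x 3 matrix of row vectors (Å).
#' @param box_edge Edge length of the cubic cell (Å), `> 0`.
#' @return Object of the same shape as `v` with every component in
#'   `[-box_edge/2, box_edge/2)`.
#' @examples
#' minimum_image(c(13, 0, 0), 14)   # -> c(-1, 0, 0)
#' @export
minimum_image <- function(v, box_edge) {
  stopifnot(is.numeric(box_edge), length(box_edge) == 1L, box_edge > 0)
  if (!all(is.finite(v))) {
    stop("invalid geometry: non-finite coordinate components", call. = FALSE)
  }
  # floor(x + 0.5) rather than round(): maps +box/2 to -box/2, keeping the
  # half-open convention exact.
  v - box_edge * floor(v / box_edge + 0.5)
}

#' Angle between two vectors
#'
#' @param u,w Numeric vectors of length 3; both must be nonzero.
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angle_between(c(1, 0, 0), c(-1, 1, 0))  # 135
#' @export
angle_between <- function(u, w) {
  nu <- sqrt(sum(u * u))
  nw <- sqrt(sum(w * w))
  if (!is.finite(nu) || !is.finite(nw) || nu == 0 || nw == 0) {
    stop("invalid geometry: zero-length or non-finite vector in angle_between",
         call. = FALSE)
  }
  ca <- sum(u * w) / (nu * nw)
  ca <- min(1, max(-1, ca))
  acos(ca) * 180 / pi
}

## ---- frame / trajectory containers -------------------------------------

#' Construct a single trajectory frame
#'
#' A frame holds the ion position, the four lone-pair sites, and the water
#' geometries at one time point. Coordinates are stored as read (possibly
#' unwrapped); every distance computed from a frame goes through
#' [minimum_image()].
#'
#' @param time Time stamp (ps).
#' @param box_edge Cubic box edge (Å).
#' @param ion_xyz Length-3 ion position (Å).
#' @param lp_xyz 4 x 3 matrix of lone-pair site positions (Å). Each site must
#'   lie within `box_edge/4` of the ion after minimum imaging.
#' @param o_xyz,h1_xyz,h2_xyz n x 3 matrices of water oxygen and hydrogen
#'   positions (Å).
#' @param water_ids Integer identifiers, unique within the frame and stable
#'   across frames of a trajectory.
#' @param region Optional character vector of generator ground-truth region
#'   labels (`"tight"`, `"loose"`, `"bulk"`); metadata only, never used by
#'   analysis code.
#' @return An object of class `lp_frame`.
#' @export
lp_frame <- function(time, box_edge, ion_xyz, lp_xyz, o_xyz, h1_xyz, h2_xyz,
                     water_ids, region = NULL) {
  ion_xyz <- as.numeric(ion_xyz)
  lp_xyz <- as.matrix(lp_xyz)
  o_xyz <- matrix(as.numeric(o_xyz), ncol = 3)
  h1_xyz <- matrix(as.numeric(h1_xyz), ncol = 3)
  h2_xyz <- matrix(as.numeric(h2_xyz), ncol = 3)
  water_ids <- as.integer(water_ids)
  stopifnot(length(ion_xyz) == 3, ncol(lp_xyz) == 3)
  if (!is.numeric(box_edge) || box_edge <= 0) {
    stop("box_edge must be a positive number", call. = FALSE)
  }
  if (nrow(lp_xyz) != 4L) {
    stop(sprintf("frame must contain exactly 4 lone-pair sites, got %d",
                 nrow(lp_xyz)), call. = FALSE)
  }
  dlp <- minimum_image(sweep(lp_xyz, 2, ion_xyz), box_edge)
  if (any(sqrt(rowSums(dlp^2)) >= box_edge / 4)) {
    stop("lone-pair site farther than box_edge/4 from the ion", call. = FALSE)
  }
  n <- nrow(o_xyz)
  stopifnot(nrow(h1_xyz) == n, nrow(h2_xyz) == n, length(water_ids) == n)
  if (anyDuplicated(water_ids)) {
    stop("water_ids must be unique within a frame", call. = FALSE)
  }
  structure(
    list(time = time, box_edge = box_edge, ion_xyz = ion_xyz, lp_xyz = lp_xyz,
         o_xyz = o_xyz, h1_xyz = h1_xyz, h2_xyz = h2_xyz,
         water_ids = water_ids, region = region),
    class = "lp_frame"
  )
}

#' Number of waters in a frame
#' @param frame An `lp_frame`.
#' @return Integer count.
#' @export
n_waters <- function(frame) nrow(frame$o_xyz)

#' Construct a trajectory from a list of frames
#'
#' @param frames List of [lp_frame()] objects in time order.
#' @param dt Time between consecutive frames (ps). Checked against the frame
#'   time stamps to within 1e-9 ps.
#' @return An object of class `lp_trajectory` with elements `frames`, `dt`,
#'   `t_sim` (time span, ps) and `box_edge`.
#' @export
lp_trajectory <- function(frames, dt) {
  stopifnot(is.list(frames), length(frames) >= 1L, dt > 0)
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L) {
    steps <- diff(times)
    if (any(steps <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
    if (any(abs(steps - dt) > 1e-9)) {
      stop("frame spacing differs from dt by more than 1e-9 ps", call. = FALSE)
    }
  }
  structure(
    list(frames = frames, dt = dt,
         t_sim = times[length(times)] - times[1],
         box_edge = frames[[1]]$box_edge),
    class = "lp_trajectory"
  )
}

#' @export
print.lp_trajectory <- function(x, ...) {
  cat(sprintf(
    "lp_trajectory: %d frames, dt = %g ps, span = %g ps, box = %g Ang, %d waters\n",
    length(x$frames), x$dt, x$t_sim, x$box_edge, n_waters(x$frames[[1]])))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `lp_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) length(traj$frames)

# Euclidean norms of rows of a matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Minimum-image ion->oxygen distances for one frame.
frame_r_xo <- function(frame) {
  row_norms(minimum_image(sweep(frame$o_xyz, 2, frame$ion_xyz), frame$box_edge))
}
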