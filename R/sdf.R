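# All 24 permutations of 1:4, built once at load time.
perms4 <- local({
  out <- matrix(NA_integer_, 24, 4)
  k <- 1L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (d in setdiff(1:4, c(a, b))) {
    out[k, ] <- c(a, b, d, setdiff(1:4, c(a, b, d)))
    k <- k + 1L
  }
  out
})

# Match current lone-pair directions to the previous frame's by maximal total
# alignment over all 24 permutations. Returns the permutation p such that
# dirs[p[i], ] corresponds to prev_dirs[i, ].
match_lp_order <- function(dirs, prev_dirs) {
  dots <- dirs %*% t(prev_dirs)    # dots[j, i] = dirs_j . prev_i
  best <- 1L
  best_s <- -Inf
  for (k in seq_len(nrow(perms4))) {
    p <- perms4[k, ]
    s <- dots[p[1], 1] + dots[p[2], 2] + dots[p[3], 3] + dots[p[4], 4]
    if (s > best_s) { best_s <- s; best <- k }
  }
  perms4[best, ]
}

#' Instantaneous lone-pair local reference frame
#'
#' Builds the rotation from box coordinates (ion-centered) into the local
#' frame defined by the lone pairs: axis 1 along ion->LP1, axis 2 in the
#' LP1-LP2 plane orthogonal to axis 1, axis 3 completing a right-handed set.
#' When `prev_dirs` is supplied, lone pairs are first re-ordered by maximal
#' alignment with the previous frame's directions, which keeps lone-pair
#' identity stable across frames regardless of input order; the first frame
#' uses input order.
#'
#' @param frame An [lp_frame()].
#' @param prev_dirs Optional 4 x 3 matrix of the previous frame's ordered
#'   lone-pair unit directions.
#' @return List with `rotation` (3 x 3; local = rotation %*% ion-centered
#'   vector), `dirs` (4 x 3 ordered unit directions) and `order` (permutation
#'   applied to the frame's lone pairs).
#' @export
lp_local_frame <- function(frame, prev_dirs = NULL) {
  stopifnot(inherits(frame, "lp_frame"))
  rel <- minimum_image(sweep(frame$lp_xyz, 2, frame$ion_xyz), frame$box_edge)
  nn <- row_norms(rel)
  if (any(nn == 0)) stop("degenerate-frame error: lone pair at the ion",
                         call. = FALSE)
  dirs <- rel / nn
  ord <- if (is.null(prev_dirs)) 1:4 else match_lp_order(dirs, prev_dirs)
  dirs <- dirs[ord, , drop = FALSE]
  e1 <- dirs[1, ]
  v2 <- dirs[2, ] - sum(dirs[2, ] * e1) * e1
  n2 <- sqrt(sum(v2^2))
  if (n2 < 1e-8) {
    stop("degenerate-frame error: first two lone pairs are collinear",
         call. = FALSE)
  }
  e2 <- v2 / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(rotation = rbind(e1, e2, e3, deparse.level = 0), dirs = dirs, order = ord)
}

#' Accumulate a spatial distribution function in the lone-pair frame
#'
#' For every frame, transforms the positions of the requested species (O, or
#' both H) of waters whose ion-oxygen distance lies in `distance_window` into
#' the instantaneous lone-pair local frame and bins them on a cubic voxel
#' grid centered on the ion. The final grid is normalized to mean density 1
#' over the occupied voxels; raw counts are kept alongside.
#'
#' @param traj An [lp_trajectory()].
#' @param voxel_size Voxel edge (Å).
#' @param half_extent Half edge of the cubic grid (Å); at most `box_edge/2`.
#' @param species `"O"` or `"H"`.
#' @param distance_window Length-2 ion-oxygen distance window (Å) selecting
#'   contributing waters.
#' @return An [lp_sdf_grid()].
#' @export
accumulate_sdf <- function(traj, voxel_size = 0.2, half_extent = 5,
                           species = c("O", "H"),
                           distance_window = c(0, 4)) {
  species <- match.arg(species)
  stopifnot(inherits(traj, "lp_trajectory"))
  if (voxel_size <= 0) stop("contract error: voxel_size must be positive",
                            call. = FALSE)
  if (half_extent > traj$box_edge / 2 + 1e-12) {
    stop("contract error: half_extent must not exceed box_edge/2", call. = FALSE)
  }
  m <- max(1L, round(2 * half_extent / voxel_size))
  counts <- array(0, c(m, m, m))
  prev <- NULL
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    lf <- lp_local_frame(f, prev)
    prev <- lf$dirs
    r_xo <- frame_r_xo(f)
    keep <- r_xo >= distance_window[1] & r_xo < distance_window[2]
    if (!any(keep)) next
    pos <- if (species == "O") f$o_xyz[keep, , drop = FALSE]
           else rbind(f$h1_xyz[keep, , drop = FALSE],
                      f$h2_xyz[keep, , drop = FALSE])
    rel <- minimum_image(sweep(pos, 2, f$ion_xyz), f$box_edge)
    loc <- rel %*% t(lf$rotation)
    idx <- floor((loc + half_extent) / voxel_size) + 1
    ok <- rowSums(idx >= 1 & idx <= m) == 3L
    idx <- idx[ok, , drop = FALSE]
    for (j in seq_len(nrow(idx))) {
      counts[idx[j, 1], idx[j, 2], idx[j, 3]] <-
        counts[idx[j, 1], idx[j, 2], idx[j, 3]] + 1
    }
  }
  occ <- counts[counts > 0]
  dens <- if (length(occ)) counts / mean(occ) else counts
  lp_sdf_grid(density = dens, voxel_size = voxel_size,
              origin = rep(-half_extent, 3), species = species,
              n_frames = n_frames(traj), counts = counts)
}

#' Count connected density maxima in an SDF grid
#'
#' Thresholds the grid at a fraction of its peak density and counts
#' 6-connected components of the resulting voxel set. On tetrahedrally
#' anchored synthetic data the oxygen SDF yields exactly four such maxima,
#' one per lone pair.
#'
#' @param grid An [lp_sdf_grid()].
#' @param frac Threshold as a fraction of the maximum density.
#' @return List with `n_clusters` and `centers` (cluster centers of mass in
#'   local-frame Å, one row per cluster).
#' @export
count_density_clusters <- function(grid, frac = 0.5) {
  stopifnot(inherits(grid, "lp_sdf_grid"), frac > 0, frac <= 1)
  v <- grid$density
  mx <- max(v)
  if (mx <= 0) return(list(n_clusters = 0L, centers = matrix(numeric(0), 0, 3)))
  dims <- dim(v)
  mask <- v >= frac * mx
  lab <- array(0L, dims)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comp <- 0L
  centers <- list()
  which_mask <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(which_mask))) {
    start <- which_mask[s, ]
    if (lab[start[1], start[2], start[3]] != 0L) next
    comp <- comp + 1L
    queue <- matrix(start, 1, 3)
    lab[start[1], start[2], start[3]] <- comp
    members <- queue
    while (nrow(queue)) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (d in seq_len(6)) {
        nxt <- cur + nb[d, ]
        if (any(nxt < 1) || any(nxt > dims)) next
        if (mask[nxt[1], nxt[2], nxt[3]] && lab[nxt[1], nxt[2], nxt[3]] == 0L) {
          lab[nxt[1], nxt[2], nxt[3]] <- comp
          queue <- rbind(queue, nxt)
          members <- rbind(members, nxt)
        }
      }
    }
    w <- v[members]
    ctr <- colSums(members * w) / sum(w)
    centers[[comp]] <- grid$origin + (ctr - 0.5) * grid$voxel_size
  }
  list(n_clusters = comp,
       centers = if (comp) do.call(rbind, centers) else matrix(numeric(0), 0, 3))
}
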