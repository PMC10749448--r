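#' Species label map for XYZ trajectories
#'
#' Names the atom labels used in an (extended) XYZ trajectory: the ion, the
#' water oxygen and hydrogens, and the pseudo-atom tag used for lone-pair /
#' Wannier-center sites.
#'
#' @param ion Ion label (e.g. `"Cl"`, `"I"`).
#' @param water_O,water_H Water oxygen / hydrogen labels.
#' @param lp Lone-pair pseudo-atom label; CPMD-style center dumps commonly
#'   use `"X"`.
#' @return A named list of class `lp_species_map`.
#' @export
species_map <- function(ion = "Cl", water_O = "O", water_H = "H", lp = "X") {
  labels <- c(ion = ion, water_O = water_O, water_H = water_H, lp = lp)
  if (anyDuplicated(labels)) {
    stop("species labels must be pairwise distinct", call. = FALSE)
  }
  structure(as.list(labels), class = "lp_species_map")
}

# Parse a multi-frame XYZ file into raw (labels, coords) frames.
parse_xyz_raw <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("XYZ format error: expected atom count at line %d", i),
           call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("XYZ format error: truncated frame at end of file", call. = FALSE)
    }
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(toks) < 4L)) {
      stop("XYZ format error: atom line with fewer than 4 fields", call. = FALSE)
    }
    labels <- vapply(toks, `[[`, character(1), 1L)
    coords <- matrix(as.numeric(unlist(lapply(toks, function(t) t[2:4]))),
                     ncol = 3, byrow = TRUE)
    if (any(!is.finite(coords))) {
      stop("XYZ format error: non-numeric coordinate field", call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- list(labels = labels, coords = coords,
                                          comment = lines[i + 1L])
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("XYZ format error: no frames found", call. = FALSE)
  frames
}

#' Read an extended XYZ trajectory with lone-pair pseudo-atoms
#'
#' Each frame must contain exactly one ion atom, lone-pair pseudo-atoms of
#' which exactly 4 lie within `box_edge/4` of the ion (pseudo-atoms near water
#' oxygens, e.g. water Wannier centers, are discarded by this proximity rule),
#' and water O/H atoms groupable into intact molecules. Hydrogens are assigned
#' to their nearest oxygen under the minimum-image metric; every oxygen must
#' receive exactly two. Water identifiers follow the first frame's oxygen
#' order and are preserved by list position across frames.
#'
#' `dt` and `box_edge` are required configuration rather than parsed from the
#' comment lines, which are not standardized across MD codes.
#'
#' @param path Path to the XYZ file.
#' @param smap A [species_map()].
#' @param dt Frame spacing (ps).
#' @param box_edge Cubic box edge (Å).
#' @return An [lp_trajectory()].
#' @export
read_xyz_trajectory <- function(path, smap = species_map(), dt, box_edge) {
  raw <- parse_xyz_raw(path)
  nat0 <- length(raw[[1]]$labels)
  frames <- vector("list", length(raw))
  for (k in seq_along(raw)) {
    fr <- raw[[k]]
    if (length(fr$labels) != nat0) {
      stop(sprintf("format error: %d atoms in frame %d but %d in frame 0",
                   length(fr$labels), k - 1L, nat0), call. = FALSE)
    }
    ion_idx <- which(fr$labels == smap$ion)
    if (length(ion_idx) != 1L) {
      stop(sprintf("format error: %d ion atoms in frame %d",
                   length(ion_idx), k - 1L), call. = FALSE)
    }
    ion <- fr$coords[ion_idx, ]
    lp_idx <- which(fr$labels == smap$lp)
    if (length(lp_idx)) {
      d <- row_norms(minimum_image(sweep(fr$coords[lp_idx, , drop = FALSE],
                                         2, ion), box_edge))
      near <- lp_idx[d < box_edge / 4]
      dn <- d[d < box_edge / 4]
    } else {
      near <- integer(0); dn <- numeric(0)
    }
    if (length(near) < 4L) {
      stop(sprintf("format error: %d lone pairs in frame %d",
                   length(near), k - 1L), call. = FALSE)
    }
    near <- near[order(dn)][1:4]
    lp <- fr$coords[sort(near), , drop = FALSE]

    o_idx <- which(fr$labels == smap$water_O)
    h_idx <- which(fr$labels == smap$water_H)
    if (!length(o_idx) || length(h_idx) != 2L * length(o_idx)) {
      stop(sprintf("format error: %d O and %d H atoms in frame %d",
                   length(o_idx), length(h_idx), k - 1L), call. = FALSE)
    }
    o <- fr$coords[o_idx, , drop = FALSE]
    h <- fr$coords[h_idx, , drop = FALSE]
    # nearest-O assignment for every hydrogen
    assign <- integer(nrow(h))
    for (j in seq_len(nrow(h))) {
      d2 <- rowSums(minimum_image(sweep(o, 2, h[j, ]), box_edge)^2)
      assign[j] <- which.min(d2)
    }
    if (any(tabulate(assign, nbins = nrow(o)) != 2L)) {
      stop(sprintf(
        "format error: hydrogen-to-oxygen assignment is not 2 per O in frame %d",
        k - 1L), call. = FALSE)
    }
    h1 <- h2 <- matrix(NA_real_, nrow(o), 3)
    for (w in seq_len(nrow(o))) {
      hw <- which(assign == w)
      h1[w, ] <- h[hw[1], ]
      h2[w, ] <- h[hw[2], ]
    }
    frames[[k]] <- lp_frame(time = (k - 1L) * dt, box_edge = box_edge,
                            ion_xyz = ion, lp_xyz = lp, o_xyz = o,
                            h1_xyz = h1, h2_xyz = h2,
                            water_ids = seq_len(nrow(o)))
  }
  lp_trajectory(frames, dt = dt)
}

#' Write a trajectory as a multi-frame extended XYZ file
#'
#' Inverse of [read_xyz_trajectory()]: one ion line, four lone-pair
#' pseudo-atom lines, then O,H,H triplets per water, in water-id order.
#'
#' @param traj An [lp_trajectory()].
#' @param path Output path.
#' @param smap A [species_map()].
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, smap = species_map()) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(lab, m) sprintf("%-3s %14.6f %14.6f %14.6f",
                                  lab, m[, 1], m[, 2], m[, 3])
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    n <- n_waters(f)
    writeLines(as.character(1L + 4L + 3L * n), con)
    writeLines(sprintf("frame %d time_ps %.9f", k - 1L, f$time), con)
    writeLines(fmt(smap$ion, matrix(f$ion_xyz, 1)), con)
    writeLines(fmt(smap$lp, f$lp_xyz), con)
    if (n) {
      ord <- order(f$water_ids)
      block <- matrix(NA_real_, 3L * n, 3)
      labs <- character(3L * n)
      for (i in seq_len(n)) {
        w <- ord[i]
        block[3 * i - 2, ] <- f$o_xyz[w, ]
        block[3 * i - 1, ] <- f$h1_xyz[w, ]
        block[3 * i, ]     <- f$h2_xyz[w, ]
        labs[(3 * i - 2):(3 * i)] <- c(smap$water_O, smap$water_H, smap$water_H)
      }
      writeLines(fmt(labs, block), con)
    }
  }
  invisible(path)
}

#' Merge a coordinates XYZ file with a separate centers XYZ file
#'
#' CPMD-style runs often dump ionic coordinates and Wannier centers in
#' separate files. This merges them frame by frame into a single extended XYZ
#' with the centers relabeled as lone-pair pseudo-atoms, the dialect
#' [read_xyz_trajectory()] consumes. Both files must contain the same number
#' of frames.
#'
#' @param coords_path,centers_path Input XYZ paths.
#' @param out_path Output path for the merged XYZ.
#' @param lp_label Label given to every center atom in the output.
#' @return `out_path`, invisibly.
#' @export
merge_centers_xyz <- function(coords_path, centers_path, out_path,
                              lp_label = "X") {
  a <- parse_xyz_raw(coords_path)
  b <- parse_xyz_raw(centers_path)
  if (length(a) != length(b)) {
    stop(sprintf("format error: %d coordinate frames but %d centers frames",
                 length(a), length(b)), call. = FALSE)
  }
  con <- file(out_path, "w")
  on.exit(close(con))
  for (k in seq_along(a)) {
    n <- length(a[[k]]$labels) + length(b[[k]]$labels)
    writeLines(as.character(n), con)
    writeLines(a[[k]]$comment, con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", a[[k]]$labels,
                       a[[k]]$coords[, 1], a[[k]]$coords[, 2], a[[k]]$coords[, 3]), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", lp_label,
                       b[[k]]$coords[, 1], b[[k]]$coords[, 2], b[[k]]$coords[, 3]), con)
  }
  invisible(out_path)
}

#' Write a two-column curve file
#'
#' Whitespace-delimited text with a `#`-prefixed header naming the quantities
#' and their units; the serialization used for g(r) and P(eta) curves.
#'
#' @param x,y Equal-length numeric vectors.
#' @param path Output path.
#' @param xlab,ylab Column names, units included (e.g. `"r [Ang]"`).
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, y, path, xlab = "x", ylab = "y") {
  if (length(x) != length(y)) {
    stop("contract error: x and y lengths differ", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s  %s", xlab, ylab), con)
  if (length(x)) writeLines(sprintf("%.8g %.8g", x, y), con)
  invisible(path)
}

#' Construct a volumetric density grid
#'
#' Container for spatial distribution functions accumulated in the lone-pair
#' local frame (ion at the origin). Cubic voxels.
#'
#' @param density 3-dimensional numeric array of voxel values.
#' @param voxel_size Voxel edge (Å).
#' @param origin Length-3 position of the corner of voxel (1,1,1) (Å);
#'   defaults to centering the grid on the origin.
#' @param species Species the densities refer to (`"O"` or `"H"`).
#' @param n_frames Number of frames accumulated.
#' @param counts Optional raw count array of the same shape.
#' @return An object of class `lp_sdf_grid`.
#' @export
lp_sdf_grid <- function(density, voxel_size,
                        origin = -dim(density) * voxel_size / 2,
                        species = "O", n_frames = NA_integer_, counts = NULL) {
  stopifnot(is.array(density), length(dim(density)) == 3, voxel_size > 0,
            length(origin) == 3)
  structure(list(density = density, voxel_size = voxel_size,
                 origin = as.numeric(origin), species = species,
                 n_frames = n_frames, counts = counts),
            class = "lp_sdf_grid")
}

#' Write a density grid in Gaussian cube format
#'
#' Axes are written in Angstrom using the negative-voxel-count convention;
#' the ion is the single atom record, at the local-frame origin. Values run
#' z-fastest, x-slowest, six per line.
#'
#' @param grid An [lp_sdf_grid()].
#' @param path Output path.
#' @param atomic_number Atomic number written for the ion record.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path, atomic_number = 17L) {
  stopifnot(inherits(grid, "lp_sdf_grid"))
  v <- grid$density
  if (!length(v)) stop("contract error: empty grid", call. = FALSE)
  dims <- dim(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("lone-pair frame spatial distribution function",
               sprintf("species %s, %s frames accumulated",
                       grid$species, grid$n_frames)), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 1L,
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", -dims[1], grid$voxel_size, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", -dims[2], 0, grid$voxel_size, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", -dims[3], 0, 0, grid$voxel_size), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                     as.integer(atomic_number), 0, 0, 0, 0), con)
  vals <- as.vector(aperm(v, c(3, 2, 1)))  # z fastest after transposition
  idx <- seq_along(vals)
  rows <- split(vals, ceiling(idx / 6))
  writeLines(vapply(rows, function(r) paste(sprintf("%13.5e", r), collapse = " "),
                    character(1)), con)
  invisible(path)
}
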