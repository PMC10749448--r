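#' Parameters for the synthetic hydration-shell trajectory generator
#'
#' The generator emulates the statistical structure the analysis assumes: an
#' anion at the box center carrying four tetrahedral lone-pair sites, up to
#' four "tight" waters hydrogen-bonded along the lone-pair directions, a
#' diffuse "loose" first shell with no orientational preference, bulk waters,
#' and Markovian inter-region exchange. It makes no attempt at physical
#' water-water forces; it is a ground-truth-labeled stand-in used to validate
#' every analysis stage.
#'
#' @param n_tight Number of tight waters (each anchored to a distinct lone
#'   pair; at most 4).
#' @param n_loose,n_bulk Initial numbers of loose and bulk waters.
#' @param box_edge Cubic box edge (Å).
#' @param d_lp Ion-to-lone-pair distance (Å). Only the lone-pair directions
#'   matter downstream; the offset just has to be much smaller than any
#'   ion-water distance.
#' @param r_tight_mean,r_tight_sd Mean and s.d. (Å) of the ion-hydrogen
#'   distance of tight waters.
#' @param r_loose_range Length-2 range (Å): loose oxygens are uniform in this
#'   spherical shell.
#' @param angular_noise_deg Standard deviation (degrees) of the tilt applied
#'   both to the lone-pair alignment of the tight O-H bond and to its O-H
#'   direction.
#' @param k_TL,k_LT,k_LB,k_BL Exchange rates (ps^-1): tight->loose,
#'   loose->tight, loose->bulk, bulk->loose. Loose->tight moves are
#'   suppressed while all four lone-pair anchors are occupied, so the tight
#'   shell never exceeds 4 waters. The default loose<->bulk pair satisfies
#'   `k_BL / (k_LB + k_BL) = n_loose / (n_loose + n_bulk)` for the default
#'   composition, so the declared shell sizes are stationary.
#' @param misoriented_fraction Per frame, fraction of loose waters whose
#'   orientation is forced to point both hydrogens away from the ion.
#' @param min_oo Smallest allowed oxygen-oxygen contact (Å). The default is
#'   the closest approach of real water oxygens; it also guarantees that
#'   every hydrogen is nearer its own oxygen than any other
#'   (`min_oo - 0.97 > 0.97`), which the nearest-O assembly of
#'   [read_xyz_trajectory()] relies on.
#' @param dt Frame spacing (ps).
#' @param n_frames Number of frames.
#' @param seed RNG seed; identical parameters give bit-identical output.
#' @param lp_rot_sd_deg Per-frame angle s.d. (degrees) of the slow random-walk
#'   rigid rotation of the lone-pair tetrahedron.
#' @return An object of class `lp_synth_params`.
#' @export
synth_params <- function(n_tight = 4, n_loose = 6, n_bulk = 20,
                         box_edge = 14, d_lp = 0.5,
                         r_tight_mean = 2.25, r_tight_sd = 0.10,
                         r_loose_range = c(3.2, 4.0),
                         angular_noise_deg = 10,
                         k_TL = 1, k_LT = 1, k_LB = 2, k_BL = 0.6,
                         misoriented_fraction = 0, min_oo = 2.4,
                         dt = 0.005, n_frames = 2000, seed = 1,
                         lp_rot_sd_deg = 2) {
  p <- list(n_tight = as.integer(n_tight), n_loose = as.integer(n_loose),
            n_bulk = as.integer(n_bulk), box_edge = box_edge, d_lp = d_lp,
            r_tight_mean = r_tight_mean, r_tight_sd = r_tight_sd,
            r_loose_range = as.numeric(r_loose_range),
            angular_noise_deg = angular_noise_deg,
            k_TL = k_TL, k_LT = k_LT, k_LB = k_LB, k_BL = k_BL,
            misoriented_fraction = misoriented_fraction, min_oo = min_oo,
            dt = dt, n_frames = as.integer(n_frames), seed = as.integer(seed),
            lp_rot_sd_deg = lp_rot_sd_deg)
  rates <- c(p$k_TL, p$k_LT, p$k_LB, p$k_BL)
  if (any(rates < 0)) stop("exchange rates must be >= 0", call. = FALSE)
  if (p$n_tight < 0 || p$n_tight > 4L) {
    stop("n_tight must be between 0 and 4 (one distinct lone-pair anchor each)",
         call. = FALSE)
  }
  if (p$n_loose < 0 || p$n_bulk < 0 || p$n_frames < 1L) {
    stop("counts must be non-negative and n_frames >= 1", call. = FALSE)
  }
  stopifnot(length(p$r_loose_range) == 2L)
  if (!(p$r_loose_range[1] > 0 && diff(p$r_loose_range) > 0 &&
        p$r_loose_range[2] <= p$box_edge / 2)) {
    stop("r_loose_range must be increasing, positive and within box_edge/2",
         call. = FALSE)
  }
  if (p$r_tight_mean <= 0 || p$r_tight_sd < 0 || p$d_lp <= 0 ||
      p$box_edge <= 0 || p$dt <= 0) {
    stop("distances, box edge and dt must be positive", call. = FALSE)
  }
  if (p$misoriented_fraction < 0 || p$misoriented_fraction > 1) {
    stop("misoriented_fraction must be in [0, 1]", call. = FALSE)
  }
  if (p$min_oo <= 0) stop("min_oo must be positive", call. = FALSE)
  class(p) <- "lp_synth_params"
  p
}

#' Preset generator parameters for the two halides
#'
#' Sets the tight-shell ion-hydrogen distance and the loose-shell range from
#' the conventional first-shell geometry of each ion (first-shell X-O
#' distance cutoffs of 4.00 and 4.37 Å; tight X-H near 2.25 and 2.6 Å).
#' The iodide preset also places a fraction of misoriented loose waters.
#'
#' @param ion `"chloride"` or `"iodide"`.
#' @param ... Overrides passed on to [synth_params()].
#' @return An `lp_synth_params` object.
#' @export
synth_preset <- function(ion = c("chloride", "iodide"), ...) {
  ion <- match.arg(ion)
  base <- if (ion == "chloride") {
    list(r_tight_mean = 2.25, r_loose_range = c(3.2, 4.0),
         misoriented_fraction = 0)
  } else {
    list(r_tight_mean = 2.60, r_loose_range = c(3.55, 4.37),
         misoriented_fraction = 0.15)
  }
  over <- list(...)
  do.call(synth_params, utils::modifyList(base, over))
}

# Base tetrahedral unit directions.
tetrahedral_dirs <- function() {
  m <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  m / sqrt(3)
}

# Rotation matrix about a unit axis by an angle in radians (Rodrigues).
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_unit <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

# A unit vector perpendicular to u at a uniformly random azimuth.
random_perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  phi <- stats::runif(1, 0, 2 * pi)
  cos(phi) * e1 + sin(phi) * e2
}

# Tilt a unit direction by an angle drawn from |N(0, sd_deg)| about a random
# perpendicular axis.
jitter_dir <- function(u, sd_deg) {
  if (sd_deg <= 0) return(u)
  ang <- abs(stats::rnorm(1, 0, sd_deg)) * pi / 180
  e <- random_perp(u)
  cos(ang) * u + sin(ang) * e
}

#' Simulate per-water region dynamics
#'
#' Runs the per-water continuous-time Markov chain of [synth_params()]
#' discretized at `dt` (per-step jump probability `1 - exp(-k dt)`), with the
#' lone-pair capacity rule: a loose->tight move is suppressed when all four
#' anchors are occupied; a committing water takes the lowest free anchor.
#' Waters are updated in id order within a step, so output is deterministic
#' for a given seed.
#'
#' @param params An `lp_synth_params` object.
#' @return List with `regions` (n_frames x n_waters character matrix with
#'   entries `"tight"`, `"loose"`, `"bulk"`) and `anchors` (same shape,
#'   integer lone-pair index or NA).
#' @export
simulate_regions <- function(params) {
  stopifnot(inherits(params, "lp_synth_params"))
  set.seed(params$seed)
  n <- params$n_tight + params$n_loose + params$n_bulk
  reg <- character(n)
  anc <- rep(NA_integer_, n)
  if (params$n_tight) {
    reg[seq_len(params$n_tight)] <- "tight"
    anc[seq_len(params$n_tight)] <- seq_len(params$n_tight)
  }
  if (params$n_loose) reg[params$n_tight + seq_len(params$n_loose)] <- "loose"
  if (params$n_bulk) reg[params$n_tight + params$n_loose + seq_len(params$n_bulk)] <- "bulk"

  regions <- matrix(NA_character_, params$n_frames, n)
  anchors <- matrix(NA_integer_, params$n_frames, n)
  regions[1, ] <- reg
  anchors[1, ] <- anc
  if (params$n_frames == 1L) return(list(regions = regions, anchors = anchors))

  p_tl <- 1 - exp(-params$k_TL * params$dt)
  k_lout <- params$k_LT + params$k_LB
  p_lout <- 1 - exp(-k_lout * params$dt)
  p_bl <- 1 - exp(-params$k_BL * params$dt)
  for (t in 2:params$n_frames) {
    for (w in seq_len(n)) {
      r <- reg[w]
      if (r == "tight") {
        if (p_tl > 0 && stats::runif(1) < p_tl) {
          reg[w] <- "loose"; anc[w] <- NA_integer_
        }
      } else if (r == "loose") {
        if (p_lout > 0 && stats::runif(1) < p_lout) {
          to_tight <- stats::runif(1) < params$k_LT / k_lout
          if (to_tight) {
            free <- setdiff(1:4, anc[!is.na(anc)])
            if (length(free)) {        # capacity rule: need a free anchor
              reg[w] <- "tight"; anc[w] <- min(free)
            }
          } else {
            reg[w] <- "bulk"
          }
        }
      } else {
        if (p_bl > 0 && stats::runif(1) < p_bl) reg[w] <- "loose"
      }
    }
    regions[t, ] <- reg
    anchors[t, ] <- anc
  }
  list(regions = regions, anchors = anchors)
}

# Place one rigid water given the O position and the O->H1 direction; the
# second hydrogen takes a uniformly random azimuth, so feeding a uniform d1
# gives a uniform rigid orientation. Internal geometry fixed: O-H 0.97 Å,
# H-O-H 104.5°.
place_water <- function(o, d1) {
  roh <- 0.97
  hoh <- 104.5 * pi / 180
  h1 <- o + roh * d1
  e <- random_perp(d1)                  # uniform azimuth around d1
  d2 <- cos(hoh) * d1 + sin(hoh) * e
  list(o = o, h1 = h1, h2 = o + roh * d2)
}

#' Generate a synthetic lone-pair hydration trajectory
#'
#' Ion at the box center; four lone pairs at `d_lp` along tetrahedral
#' directions, rigidly rotated by a slow random walk across frames. Tight
#' waters are placed with one O-H bond pointing at their assigned lone pair
#' (within `angular_noise_deg`) and ion-H distance drawn from
#' `N(r_tight_mean, r_tight_sd)`; loose waters are uniform in the
#' `r_loose_range` shell with random orientation (a `misoriented_fraction`
#' forced to point both hydrogens away from the ion); bulk waters are uniform
#' between the loose shell and the inscribed sphere of the box. Regions evolve
#' per [simulate_regions()] and geometry is resampled for the current region
#' every frame. Oxygen-oxygen contacts closer than `min_oo` (minimum-image
#' metric) are rejected and resampled; a water that cannot be placed after
#' 100 attempts triggers a deterministic position sweep and, failing that, a
#' re-pack of the whole frame, before an overfull shell raises a generation
#' error.
#'
#' The ground-truth regions are carried in each frame's `region` field and in
#' the trajectory's `regions` matrix for label-recovery tests; analysis stages
#' never read them.
#'
#' @param params An `lp_synth_params` object.
#' @return An [lp_trajectory()] with extra elements `regions`, `anchors` and
#'   `params`.
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "lp_synth_params"))
  sim <- simulate_regions(params)  # seeds the RNG with params$seed
  n <- ncol(sim$regions)
  ion <- rep(params$box_edge / 2, 3)
  tet <- tetrahedral_dirs()
  rot <- diag(3)
  r3lo <- params$r_loose_range[1]^3
  r3hi <- params$r_loose_range[2]^3
  rb_lo3 <- params$r_loose_range[2]^3
  rb_hi3 <- (params$box_edge / 2)^3
  half_hoh <- 104.5 / 2 * pi / 180

  frames <- vector("list", params$n_frames)
  for (t in seq_len(params$n_frames)) {
    if (params$lp_rot_sd_deg > 0) {
      rot <- rotation_about(random_unit(),
                            stats::rnorm(1, 0, params$lp_rot_sd_deg) * pi / 180) %*% rot
    }
    dirs <- tet %*% t(rot)                       # current lone-pair directions
    lp <- sweep(params$d_lp * dirs, 2, ion, `+`)
    # tight sites are nearly rigid, so place them first; loose and bulk
    # waters are resampled around them on overlap. A frame whose sequential
    # packing dead-ends (transiently crowded loose shell) is re-packed from
    # scratch with fresh randomness before the shell is declared overfull.
    reg_t <- sim$regions[t, ]
    ord_w <- order(match(reg_t, c("tight", "loose", "bulk")))
    frame_done <- FALSE
    failed_water <- NA_integer_
    for (frame_try in 1:25) {
    o_m <- h1_m <- h2_m <- matrix(NA_real_, n, 3)
    placed <- matrix(numeric(0), 0, 3)
    frame_done <- TRUE
    for (w in ord_w) {
      r <- reg_t[w]
      ok <- FALSE
      for (attempt in 1:100) {
        if (r == "tight") {
          a <- sim$anchors[t, w]
          u <- jitter_dir(dirs[a, ], params$angular_noise_deg)
          rh <- stats::rnorm(1, params$r_tight_mean, params$r_tight_sd)
          if (rh <= params$d_lp + 0.1) next
          h1 <- ion + rh * u
          w0 <- h1 - lp[a, ]
          w0 <- w0 / sqrt(sum(w0^2))
          d_oh <- jitter_dir(w0, params$angular_noise_deg)
          o <- h1 + 0.97 * d_oh
          # H1 is prescribed here; rebuild the molecule around it
          e <- random_perp(-d_oh)
          d2 <- cos(104.5 * pi / 180) * (-d_oh) + sin(104.5 * pi / 180) * e
          wtr <- list(o = o, h1 = h1, h2 = o + 0.97 * d2)
        } else if (r == "loose") {
          ro <- (stats::runif(1, r3lo, r3hi))^(1 / 3)
          o <- ion + ro * random_unit()
          if (params$misoriented_fraction > 0 &&
              stats::runif(1) < params$misoriented_fraction) {
            b <- (o - ion) / ro                   # outward radial direction
            e <- random_perp(b)
            d1 <- cos(half_hoh) * b + sin(half_hoh) * e
            d2 <- cos(half_hoh) * b - sin(half_hoh) * e
            wtr <- list(o = o, h1 = o + 0.97 * d1, h2 = o + 0.97 * d2)
          } else {
            wtr <- place_water(o, random_unit())
          }
        } else {
          ro <- (stats::runif(1, rb_lo3, rb_hi3))^(1 / 3)
          o <- ion + ro * random_unit()
          wtr <- place_water(o, random_unit())
        }
        if (!nrow(placed) ||
            min(rowSums(minimum_image(sweep(placed, 2, wtr$o),
                                      params$box_edge)^2)) >= params$min_oo^2) {
          ok <- TRUE
          break
        }
      }
      if (!ok && r != "tight") {
        # crowded shell: sweep a deterministic radius x direction grid for a
        # free spot before declaring the shell overfull
        rng <- if (r == "loose") params$r_loose_range
               else c(params$r_loose_range[2], params$box_edge / 2)
        golden <- pi * (3 - sqrt(5))
        for (ro in seq(rng[1] + 0.02, rng[2] - 0.02, length.out = 8)) {
          for (j in seq_len(300)) {
            z <- 1 - 2 * (j - 0.5) / 300
            th <- golden * j
            dirv <- c(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
            o <- ion + ro * dirv
            if (!nrow(placed) ||
                min(rowSums(minimum_image(sweep(placed, 2, o),
                                          params$box_edge)^2)) >= params$min_oo^2) {
              if (r == "loose" && params$misoriented_fraction > 0 &&
                  stats::runif(1) < params$misoriented_fraction) {
                b <- dirv
                e <- random_perp(b)
                d1 <- cos(half_hoh) * b + sin(half_hoh) * e
                d2 <- cos(half_hoh) * b - sin(half_hoh) * e
                wtr <- list(o = o, h1 = o + 0.97 * d1, h2 = o + 0.97 * d2)
              } else {
                wtr <- place_water(o, random_unit())
              }
              ok <- TRUE
              break
            }
          }
          if (ok) break
        }
      }
      if (!ok) {
        frame_done <- FALSE
        failed_water <- w
        break                       # re-pack the whole frame
      }
      placed <- rbind(placed, wtr$o)
      o_m[w, ] <- wtr$o
      h1_m[w, ] <- wtr$h1
      h2_m[w, ] <- wtr$h2
    }
    if (frame_done) break
    }
    if (!frame_done) {
      stop(sprintf(
        "generation error: could not place water %d in frame %d without O-O overlap",
        failed_water, t - 1L), call. = FALSE)
    }
    frames[[t]] <- lp_frame(time = (t - 1L) * params$dt,
                            box_edge = params$box_edge, ion_xyz = ion,
                            lp_xyz = lp, o_xyz = o_m, h1_xyz = h1_m,
                            h2_xyz = h2_m, water_ids = seq_len(n),
                            region = sim$regions[t, ])
  }
  traj <- lp_trajectory(frames, dt = params$dt)
  traj$regions <- sim$regions
  traj$anchors <- sim$anchors
  traj$params <- params
  traj
}

#' Generate synthetic ion-water pair interaction energies
#'
#' Linear-in-eta energies with Gaussian noise, emulating the DFT pair-energy
#' table consumed by the regression stage:
#' `E_i = slope * eta_i + intercept + N(0, noise_sd)`.
#'
#' @param etas Nonempty numeric vector of eta values (Å).
#' @param slope Slope (kJ/mol per Å).
#' @param intercept Intercept (kJ/mol).
#' @param noise_sd Noise standard deviation (kJ/mol).
#' @param seed RNG seed.
#' @return Numeric vector of energies (kJ/mol).
#' @export
generate_pair_energies <- function(etas, slope, intercept, noise_sd, seed = 1) {
  if (!length(etas)) stop("contract error: etas must be nonempty", call. = FALSE)
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  slope * etas + intercept + stats::rnorm(length(etas), 0, noise_sd)
}
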