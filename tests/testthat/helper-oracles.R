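# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately avoid the package's internal code paths.

# Minimum image by exhaustive search over lattice translations.
bf_minimum_image <- function(v, box, span = 3) {
  out <- numeric(3)
  for (i in 1:3) {
    imgs <- v[i] + box * (-span:span)
    cand <- imgs[abs(imgs) == min(abs(imgs))]
    # half-open convention: prefer the negative representative at +box/2
    out[i] <- if (length(cand) > 1) min(cand) else cand
  }
  out
}

# Raw angle (degrees) without the package's helper.
bf_angle <- function(u, w) {
  c0 <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  acos(max(-1, min(1, c0))) * 180 / pi
}

# Independent recomputation of the pair geometry and eta for one
# (water, lone pair, hydrogen) combination.
bf_pair_eta <- function(frame, w, l, h) {
  box <- frame$box_edge
  mi <- function(v) v - box * floor(v / box + 0.5)
  ion <- frame$ion_xyz
  H <- if (h == 1) frame$h1_xyz[w, ] else frame$h2_xyz[w, ]
  O <- frame$o_xyz[w, ]
  LP <- frame$lp_xyz[l, ]
  r_lp_h <- sqrt(sum(mi(H - LP)^2))
  alpha <- bf_angle(mi(LP - ion), mi(H - ion))
  beta <- bf_angle(mi(H - O), mi(LP - H))
  eta <- r_lp_h / (cos(alpha * pi / 360) * cos(beta * pi / 360))
  list(r_lp_h = r_lp_h, alpha = alpha, beta = beta, eta = eta)
}

# Eight-way minimization oracle.
bf_eta_min <- function(frame, w) {
  best <- NULL
  for (l in 1:4) for (h in 1:2) {
    pe <- bf_pair_eta(frame, w, l, h)
    if (is.null(best) || pe$eta < best$eta) {
      best <- c(pe, list(lp_index = l, h_index = h))
    }
  }
  best
}

# Naive per-frame distance histogram (counts only).
bf_rdf_counts <- function(traj, pair_kind, bin_width, r_max) {
  nb <- floor(r_max / bin_width + 1e-9)
  counts <- numeric(nb)
  for (f in traj$frames) {
    box <- f$box_edge
    mi <- function(v) v - box * floor(v / box + 0.5)
    pos <- if (pair_kind == "XO") f$o_xyz else rbind(f$h1_xyz, f$h2_xyz)
    for (j in seq_len(nrow(pos))) {
      d <- sqrt(sum(mi(pos[j, ] - f$ion_xyz)^2))
      if (d < r_max) {
        b <- floor(d / bin_width) + 1
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# Brute-force transient filter: explicit scan, testing the return window of
# every raw change and erasing discarded excursions before continuing.
bf_committed <- function(regions, dt, threshold, t0 = 0) {
  times <- t0 + (seq_along(regions) - 1) * dt
  res <- data.frame(t_leave = numeric(0), from = character(0),
                    to = character(0))
  cur <- regions[1]
  i <- 2
  while (i <= length(regions)) {
    if (regions[i] == cur) { i <- i + 1; next }
    # candidate change; look for a return to `cur` within (t, t+threshold]
    ret_idx <- NA
    j <- i + 1
    while (j <= length(regions) && times[j] <= times[i] + threshold + 1e-12) {
      if (regions[j] == cur) { ret_idx <- j; break }
      j <- j + 1
    }
    if (!is.na(ret_idx)) {
      i <- ret_idx
    } else {
      res <- rbind(res, data.frame(t_leave = times[i], from = cur,
                                   to = regions[i]))
      cur <- regions[i]
      i <- i + 1
    }
  }
  res
}

# Brute-force event walker: pairs each endpoint departure with its
# resolution; counts undirected Table-style categories.
bf_event_counts <- function(path) {
  # path: committed region sequence (consecutive entries differ)
  counts <- c("T-L" = 0, "L-B" = 0, "T-B" = 0, "T-L-B" = 0)
  lab <- c(tight = "T", bulk = "B")
  settle <- which(path != "loose")
  if (!length(settle)) return(counts)
  if (settle[1] > 1) {                       # starts loose: resolve by arrival
    dest <- path[settle[1]]
    key <- if (dest == "tight") "T-L" else "L-B"
    counts[key] <- counts[key] + 1
  }
  if (length(settle) > 1) {
    for (k in seq_len(length(settle) - 1)) {
      a <- settle[k]; b <- settle[k + 1]
      if (b == a + 1) {
        counts["T-B"] <- counts["T-B"] + 1
      } else if (path[a] == path[b]) {
        key <- if (path[a] == "tight") "T-L" else "L-B"
        counts[key] <- counts[key] + 1
      } else {
        counts["T-L-B"] <- counts["T-L-B"] + 1
      }
    }
  }
  if (settle[length(settle)] < length(path)) {  # unresolved trailing departure
    key <- if (path[settle[length(settle)]] == "tight") "T-L" else "L-B"
    counts[key] <- counts[key] + 1
  }
  counts
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal hand-built frame: ion at center of a 14 Angstrom box, lone pairs
# along given unit directions, waters given as a list of
# list(o =, h1 =, h2 =) ion-relative coordinates.
make_frame <- function(waters, lp_dirs = NULL, box = 14, d_lp = 0.5,
                       time = 0) {
  if (is.null(lp_dirs)) {
    lp_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  }
  ion <- rep(box / 2, 3)
  n <- length(waters)
  o <- t(vapply(waters, function(w) ion + w$o, numeric(3)))
  h1 <- t(vapply(waters, function(w) ion + w$h1, numeric(3)))
  h2 <- t(vapply(waters, function(w) ion + w$h2, numeric(3)))
  lp_frame(time = time, box_edge = box, ion_xyz = ion,
           lp_xyz = sweep(d_lp * lp_dirs, 2, ion, `+`),
           o_xyz = o, h1_xyz = h1, h2_xyz = h2, water_ids = seq_len(n))
}

# A rigid water with one O-H pointing from `o_rel` toward the target
# direction; all coordinates ion-relative.
water_pointing <- function(o_rel, h_dir, roh = 0.97, hoh = 104.5) {
  h_dir <- h_dir / sqrt(sum(h_dir^2))
  ref <- if (abs(h_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e <- ref - sum(ref * h_dir) * h_dir
  e <- e / sqrt(sum(e^2))
  d2 <- cos(hoh * pi / 180) * h_dir + sin(hoh * pi / 180) * e
  list(o = o_rel, h1 = o_rel + roh * h_dir, h2 = o_rel + roh * d2)
}

# Access to the internal vectorized per-frame eta path.
frame_eta_table_for_test <- function(frame) lpshells:::frame_eta(frame)
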