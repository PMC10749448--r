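test_that("eta_value satisfies its monotonicity and linear-limit contract", {
  # linear limit: both angular weights are 1, eta equals the distance
  expect_equal(eta_value(2.0, 0, 0), 2.0)
  # strictly increasing in r at fixed angles
  expect_gt(eta_value(4.0, 30, 40), eta_value(2.0, 30, 40))
  r <- stats::runif(20, 0.5, 6)
  expect_true(all(eta_value(2 * r, 25, 10) > eta_value(r, 25, 10)))
  # minimized at the linear configuration, non-decreasing away from it
  etas_a <- eta_value(2.0, seq(0, 175, by = 5), 0)
  expect_true(all(diff(etas_a) > 0))
  etas_b <- eta_value(2.0, 40, seq(0, 175, by = 5))
  expect_true(all(diff(etas_b) > 0))
  expect_true(all(etas_a[-1] > eta_value(2.0, 0, 0)))
  # domain errors, not silent clamping
  expect_error(eta_value(2.0, -1, 0), "domain error")
  expect_error(eta_value(2.0, 0, 180), "domain error")
  expect_error(eta_value(-1, 0, 0), "domain error")
})

test_that("pair_geometry reproduces the canonical hydrogen-bond configurations", {
  # ideal linear H-bond along lone pair 1: H on the LP axis, O behind H
  u <- c(1, 1, 1) / sqrt(3)
  f <- make_frame(list(list(o = 3.22 * u, h1 = 2.25 * u,
                            h2 = 3.22 * u + 0.97 * c(1, -1, 0) / sqrt(2))))
  pg <- pair_geometry(f, 1, 1, 1)
  expect_equal(pg$alpha, 0, tolerance = 1e-8)
  expect_equal(pg$beta, 0, tolerance = 1e-8)
  expect_equal(pg$r_lp_h, 2.25 - 0.5, tolerance = 1e-10)
  expect_equal(pg$eta, 1.75, tolerance = 1e-8)
  expect_equal(pg$r_xh, 2.25, tolerance = 1e-10)
  expect_equal(pg$r_xo, 3.22, tolerance = 1e-10)

  # H perpendicular to the LP axis at the ion: alpha = 90
  v <- c(1, -1, 0) / sqrt(2)          # orthogonal to u
  f2 <- make_frame(list(list(o = 3 * v, h1 = 2.1 * v, h2 = 3 * v + 0.97 * u)))
  expect_equal(pair_geometry(f2, 1, 1, 1)$alpha, 90, tolerance = 1e-8)
})

test_that("pair_geometry matches an independent brute-force recomputation", {
  p <- synth_preset("chloride", n_frames = 6, seed = 19)
  tr <- generate_trajectory(p)
  set.seed(6)
  for (rep in 1:40) {
    f <- tr$frames[[sample(n_frames(tr), 1)]]
    w <- sample(n_waters(f), 1)
    l <- sample(4, 1); h <- sample(2, 1)
    pg <- pair_geometry(f, w, l, h)
    bf <- bf_pair_eta(f, w, l, h)
    expect_equal(pg$r_lp_h, bf$r_lp_h, tolerance = 1e-10)
    expect_equal(pg$alpha, bf$alpha, tolerance = 1e-10)
    expect_equal(pg$beta, bf$beta, tolerance = 1e-10)
    expect_equal(pg$eta, bf$eta, tolerance = 1e-10)
  }
})

test_that("eta_ion_water is the 8-way minimum with lexicographic tie-breaking", {
  p <- synth_preset("chloride", n_frames = 5, seed = 23)
  tr <- generate_trajectory(p)
  for (f in tr$frames[c(1, 3, 5)]) {
    fe <- frame_eta_table_for_test(f)
    for (w in seq_len(n_waters(f))) {
      bf <- bf_eta_min(f, w)
      ew <- eta_ion_water(f, w)
      expect_equal(ew$eta, bf$eta, tolerance = 1e-10)
      expect_equal(ew$lp_index, bf$lp_index)
      expect_equal(ew$h_index, bf$h_index)
      # fast vectorized path agrees with the scalar path
      expect_equal(fe$eta[w], ew$eta, tolerance = 1e-10)
      expect_equal(fe$lp_index[w], ew$lp_index)
    }
  }
  # symmetric double contact: H1 equidistant/equiangular between LP1 and LP2
  u1 <- c(1, 1, 1) / sqrt(3); u2 <- c(1, -1, -1) / sqrt(3)
  mid <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  f2 <- make_frame(list(list(o = 3.5 * mid, h1 = 2.5 * mid,
                             h2 = 3.5 * mid + 0.97 * c(0, 1, -1) / sqrt(2))))
  ew <- eta_ion_water(f2, 1)
  e1 <- pair_geometry(f2, 1, 1, 1)$eta
  e2 <- pair_geometry(f2, 1, 2, 1)$eta
  expect_equal(e1, e2, tolerance = 1e-9)
  expect_equal(ew$lp_index, 1L)       # tie resolves to the smaller index
})

test_that("eta is invariant under rigid rotation, translation and lone-pair relabeling", {
  # waters kept inside half the box edge: beyond it the minimum image of the
  # lone-pair-hydrogen vector can wrap through the (non-rotating) lattice
  p <- synth_preset("chloride", n_frames = 3, n_bulk = 0, seed = 29)
  tr <- generate_trajectory(p)
  f <- tr$frames[[2]]
  base <- vapply(seq_len(n_waters(f)), function(w) eta_ion_water(f, w)$eta,
                 numeric(1))
  set.seed(9)
  R <- random_rotation()
  shift <- c(14, -28, 14)             # lattice translation
  g <- f
  ctr <- f$ion_xyz
  rotate <- function(m) sweep((sweep(m, 2, ctr) %*% t(R)), 2, ctr + shift, `+`)
  g$ion_xyz <- ctr + shift
  for (nm in c("lp_xyz", "o_xyz", "h1_xyz", "h2_xyz")) g[[nm]] <- rotate(f[[nm]])
  g$lp_xyz <- g$lp_xyz[c(3, 1, 4, 2), ]     # relabel lone pairs
  rotated <- vapply(seq_len(n_waters(g)), function(w) eta_ion_water(g, w)$eta,
                    numeric(1))
  expect_equal(rotated, base, tolerance = 1e-9)
})

test_that("eta distributions are normalized and the rank selections partition 7 waters", {
  p <- synth_preset("chloride", n_frames = 100, seed = 37)
  tr <- generate_trajectory(p)
  tab <- eta_table(tr)
  d_all <- eta_distribution(tab, "all")
  expect_equal(sum(d_all$p) * d_all$bin_width, 1, tolerance = 1e-9)
  rmax <- ceiling(max(tab$eta))
  d14 <- eta_distribution(tab, "rank14", r_range = c(0, rmax))
  d57 <- eta_distribution(tab, "rank57", r_range = c(0, rmax))
  expect_equal(d14$n_samples, 4 * n_frames(tr))
  expect_equal(d57$n_samples, 3 * n_frames(tr))
  expect_equal(d14$n_samples + d57$n_samples, 7 * n_frames(tr))
  expect_error(eta_distribution(tab, rep(FALSE, nrow(tab))), "empty selection")
})

test_that("identical tight geometries give a single occupied eta bin", {
  p <- synth_params(n_tight = 4, n_loose = 0, n_bulk = 0,
                    angular_noise_deg = 0, r_tight_sd = 0,
                    k_TL = 0, k_LT = 0, k_LB = 0, k_BL = 0,
                    lp_rot_sd_deg = 0, n_frames = 10, seed = 3)
  tr <- generate_trajectory(p)
  d <- eta_distribution(tr, "all")
  expect_equal(sum(d$p > 0), 1L)
  expect_equal(d$eta_centers[d$p > 0], 1.75, tolerance = 0.02)
})

test_that("the rank-distribution intersection reproduces an analytic Gaussian crossing", {
  bw <- 0.02
  centers <- seq(bw / 2, 6, by = bw)
  g1 <- stats::dnorm(centers, 2.0, 0.2)
  g2 <- stats::dnorm(centers, 3.5, 0.5)
  d14 <- eta_distribution_obj(centers, g1, "rank14")
  d57 <- eta_distribution_obj(centers, g2, "rank57")
  # analytic crossing between the means, computed independently
  crossing <- stats::uniroot(function(x) stats::dnorm(x, 2.0, 0.2) -
                               stats::dnorm(x, 3.5, 0.5),
                             c(2.0, 3.5))$root
  expect_equal(eta_cutoff_from_intersection(d14, d57), crossing,
               tolerance = bw + 1e-9)
  # identical distributions: no positive-to-negative change
  expect_error(eta_cutoff_from_intersection(d14, d14), "no-intersection")
  # disjoint supports
  h1 <- ifelse(centers < 2, 1, 0); h1 <- h1 / (sum(h1) * bw)
  h2 <- ifelse(centers > 4, 1, 0); h2 <- h2 / (sum(h2) * bw)
  expect_error(eta_cutoff_from_intersection(
    eta_distribution_obj(centers, h1), eta_distribution_obj(centers, h2)),
    "no-intersection")
})

test_that("eta_peak finds spikes, Gaussian modes and resolves ties low", {
  bw <- 0.02
  centers <- seq(bw / 2, 6, by = bw)
  spike <- numeric(length(centers)); spike[100] <- 1 / bw
  expect_equal(eta_peak(eta_distribution_obj(centers, spike)), centers[100])
  # histogram of Gaussian samples peaks near the mean
  set.seed(11)
  x <- stats::rnorm(20000, 2.5, 0.3)
  tab <- data.frame(frame = 1, eta = x, r_xo = 1)
  d <- eta_distribution(tab, rep(TRUE, length(x)), bin_width = 0.05)
  expect_equal(eta_peak(d), 2.5, tolerance = 0.08)
  bim <- numeric(length(centers)); bim[c(50, 200)] <- 1
  expect_equal(eta_peak(eta_distribution_obj(centers, bim / (sum(bim) * bw))),
               centers[50])
})
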