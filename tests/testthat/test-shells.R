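# Deterministically separable configuration: tight eta is exactly 1.75 at
# zero noise, any loose water has eta > 2.13, bulk eta > 2.5, so a cutoff at
# 2.0 recovers the generator labels exactly.
separable_params <- function(n_frames = 60, seed = 61, ...) {
  synth_params(n_tight = 4, n_loose = 5, n_bulk = 8,
               angular_noise_deg = 0, r_tight_sd = 0,
               r_loose_range = c(3.6, 4.0),
               k_TL = 0, k_LT = 0, k_LB = 0, k_BL = 0,
               n_frames = n_frames, seed = seed, ...)
}

test_that("separable synthetic labels are recovered exactly", {
  tr <- generate_trajectory(separable_params())
  lab <- classify_shells(tr, shell_cutoffs(r_cut = 4.0, eta_cut = 2.0))
  expect_equal(lab$region, as.vector(t(tr$regions)))
  # exactly n_tight waters fall below any cutoff between the tight eta value
  # and the minimum loose eta
  for (cut in c(1.8, 1.9, 2.1)) {
    lab2 <- classify_shells(tr, shell_cutoffs(4.0, cut))
    expect_true(all(tapply(lab2$region == "tight", lab2$frame, sum) == 4))
  }
})

test_that("classification at generator defaults recovers > 95% of ground truth", {
  p <- synth_preset("chloride", n_frames = 400, seed = 67)
  tr <- generate_trajectory(p)
  lab <- classify_shells(tr, shell_cutoffs(r_cut = 4.0, eta_cut = 2.5))
  acc <- mean(lab$region == as.vector(t(tr$regions)))
  expect_gt(acc, 0.95)
})

test_that("boundary waters take the outer region and far-tight waters stay tight", {
  # a water exactly at r_cut is bulk (half-open convention), even though a
  # strongly aligned water beyond r_cut would still be tight
  u <- c(1, 1, 1) / sqrt(3)
  w_at <- water_pointing(c(4, 0, 0), c(1, 0, 0))  # O exactly at r_cut, H away
  w_far <- list(o = 4.4 * u, h1 = 3.43 * u,
                h2 = 4.4 * u + 0.97 * c(1, -1, 0) / sqrt(2))  # O-H onto LP1
  f <- make_frame(list(w_at, w_far))
  tr <- lp_trajectory(list(f), dt = 0.005)
  lab <- classify_shells(tr, shell_cutoffs(r_cut = 4.0, eta_cut = 3.0))
  expect_equal(lab$region[1], "bulk")
  # far water: r_lp_h = 3.43 - 0.5 = 2.93 < 3.0 at perfect linearity
  expect_equal(lab$region[2], "tight")
  expect_gt(lab$r_xo[2], 4.0)
})

test_that("per-frame partition identities hold on noisy data", {
  p <- synth_preset("chloride", n_frames = 150, seed = 71)
  tr <- generate_trajectory(p)
  lab <- classify_shells(tr, shell_cutoffs(4.0, 2.5))
  for (k in unique(lab$frame)) {
    sub <- lab[lab$frame == k, ]
    expect_equal(nrow(sub), n_waters(tr$frames[[k]]))
    # |{r < r_cut}| = loose + |{tight and r < r_cut}|
    expect_equal(sum(sub$r_xo < 4.0),
                 sum(sub$region == "loose") +
                   sum(sub$region == "tight" & sub$r_xo < 4.0))
  }
})

test_that("raising the eta cutoff never shrinks the tight shell", {
  p <- synth_preset("chloride", n_frames = 80, seed = 73)
  tr <- generate_trajectory(p)
  cuts <- c(1.8, 2.2, 2.6, 3.0)
  labs <- lapply(cuts, function(ec)
    classify_shells(tr, shell_cutoffs(4.0, ec)))
  for (i in seq_len(length(cuts) - 1)) {
    a <- labs[[i]]$region == "tight"
    b <- labs[[i + 1]]$region == "tight"
    expect_true(all(b[a]))        # set inclusion row-wise
  }
})

test_that("coordination-number distributions match construction and recounting", {
  tr <- generate_trajectory(separable_params(n_frames = 40))
  lab <- classify_shells(tr, shell_cutoffs(4.0, 2.0))
  cnd <- cn_distribution(lab, "tight")
  expect_equal(cnd$p[cnd$n == 4], 1)
  expect_equal(sum(cnd$p), 1)
  expect_equal(cn_mode(cnd), 4L)
  # all-bulk trajectory: tight occupancy is always zero
  pb <- synth_params(n_tight = 0, n_loose = 0, n_bulk = 10,
                     k_TL = 0, k_LT = 0, k_LB = 0, k_BL = 0,
                     n_frames = 10, seed = 3)
  trb <- generate_trajectory(pb)
  labb <- classify_shells(trb, shell_cutoffs(4.0, 2.5))
  cndb <- cn_distribution(labb, "tight")
  expect_equal(cndb$p[cndb$n == 0], 1)
  # active exchange: distribution equals a direct per-frame recount
  pa <- synth_preset("chloride", n_frames = 120, seed = 79)
  tra <- generate_trajectory(pa)
  laba <- classify_shells(tra, shell_cutoffs(4.0, 2.5))
  cna <- cn_distribution(laba, "tight")
  counts <- tapply(laba$region == "tight", laba$frame, sum)
  for (i in seq_len(nrow(cna))) {
    expect_equal(cna$p[i], mean(counts == cna$n[i]))
  }
})

test_that("misorientation flags orientation hemispheres correctly", {
  u <- c(0, 0, 1)
  # one H aimed at the ion: not misoriented
  f1 <- make_frame(list(water_pointing(3.5 * u, -u)))
  expect_false(flag_misoriented(f1, 1, 4.0))
  # both H pointing away (dipole inverted): misoriented
  b <- u
  e <- c(1, 0, 0)
  half <- 104.5 / 2 * pi / 180
  d1 <- cos(half) * b + sin(half) * e
  d2 <- cos(half) * b - sin(half) * e
  f2 <- make_frame(list(list(o = 3.5 * u, h1 = 3.5 * u + 0.97 * d1,
                             h2 = 3.5 * u + 0.97 * d2)))
  expect_true(flag_misoriented(f2, 1, 4.0))
  expect_error(flag_misoriented(f2, 1, 3.0), "outside r_cut")
})

test_that("misoriented fraction of random orientations matches geometry oracle and solid angle", {
  set.seed(17)
  nf <- 400
  rigid_random_water <- function(o_rel) {
    z <- stats::runif(1, -1, 1); phi <- stats::runif(1, 0, 2 * pi)
    d1 <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    ref <- if (abs(d1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * d1) * d1; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d1[2] * e1[3] - d1[3] * e1[2], d1[3] * e1[1] - d1[1] * e1[3],
            d1[1] * e1[2] - d1[2] * e1[1])
    a <- stats::runif(1, 0, 2 * pi)           # uniform azimuth for H2
    gam <- 104.5 * pi / 180
    d2 <- cos(gam) * d1 + sin(gam) * (cos(a) * e1 + sin(a) * e2)
    list(o = o_rel, h1 = o_rel + 0.97 * d1, h2 = o_rel + 0.97 * d2)
  }
  frames <- lapply(seq_len(nf), function(k) {
    make_frame(list(rigid_random_water(c(3.5, 0, 0))), time = (k - 1) * 0.01)
  })
  tr <- lp_trajectory(frames, dt = 0.01)
  flags <- vapply(tr$frames, function(f) flag_misoriented(f, 1, 4.0), logical(1))
  # brute-force recomputation from raw coordinates
  bf <- vapply(tr$frames, function(f) {
    o2i <- f$ion_xyz - f$o_xyz[1, ]
    a1 <- bf_angle(f$h1_xyz[1, ] - f$o_xyz[1, ], o2i)
    a2 <- bf_angle(f$h2_xyz[1, ] - f$o_xyz[1, ], o2i)
    a1 > 90 && a2 > 90
  }, logical(1))
  expect_equal(flags, bf)
  # analytic fraction: both fixed-separation directions in a random
  # hemisphere, P = 1/2 - gamma/(2*pi)
  p_exp <- 0.5 - (104.5 * pi / 180) / (2 * pi)
  se <- sqrt(p_exp * (1 - p_exp) / nf)
  expect_lt(abs(mean(flags) - p_exp), 3 * se)
})

test_that("misoriented loose waters keep their loose label but carry the flag", {
  p <- synth_preset("iodide", n_frames = 100, seed = 83,
                    misoriented_fraction = 0.5)
  tr <- generate_trajectory(p)
  lab <- classify_shells(tr, shell_cutoffs(r_cut = 4.37, eta_cut = 3.0))
  gt_loose <- as.vector(t(tr$regions)) == "loose"
  mis <- lab$misoriented %in% TRUE & gt_loose
  expect_gt(sum(mis), 0)
  expect_true(all(lab$region[mis] %in% c("loose", "bulk")))
  expect_gt(mean(lab$region[mis] == "loose"), 0.9)
  # misoriented waters never classify as tight
  expect_false(any(lab$region[lab$misoriented %in% TRUE] == "tight"))
})

test_that("shell-decomposed g(r) components are exact partitions with the expected shapes", {
  # loose oxygens start at 3.6 Angstrom, so any loose eta is at least
  # 3.6 - 0.97 - 0.5 = 2.13 and a 2.05 cutoff admits no loose water into the
  # tight mask by construction
  p <- synth_preset("chloride", n_frames = 120, seed = 89,
                    r_loose_range = c(3.6, 4.0))
  tr <- generate_trajectory(p)
  lab <- classify_shells(tr, shell_cutoffs(4.0, 2.05))
  dec <- decomposed_rdf(tr, lab, bin_width = 0.05)
  expect_equal(dec$tight$g + dec$loose_bulk$g, dec$total$g, tolerance = 1e-12)
  # tight component vanishes beyond the generator mean + 4 sigma (plus the
  # O-H bond length that separates the O from the anchored hydrogen)
  r_lim <- p$r_tight_mean + 0.97 + 4 * p$r_tight_sd + 0.15
  expect_true(all(dec$tight$g[dec$tight$r_centers > r_lim] == 0))
  # and peaks near the tight ion-O distance
  pk <- dec$tight$r_centers[which.max(dec$tight$g)]
  expect_equal(pk, p$r_tight_mean + 0.97, tolerance = 0.1)
})
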