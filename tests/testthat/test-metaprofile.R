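# Metaprofile construction, normalization, rescaling, smoothing, summit
# localization and compaction estimation.

test_that("fragment midpoints land in the expected strand-oriented bin", {
  sites_p <- tiny_sites(10150L, "+")
  fr <- make_frags(10100L, 10200L)  # midpoint 10150 = offset 0
  prof <- fragment_center_profile(fr, sites_p)
  expect_equal(sum(prof$signal), 1)
  expect_equal(which(prof$signal > 0), 51L)  # bin covering [0, 10)
  expect_equal(prof$bin_centers[51L], 5)

  sites_m <- tiny_sites(10150L, "-")
  prof_m <- fragment_center_profile(fr, sites_m)
  expect_equal(which(prof_m$signal > 0), 51L)  # offset 0 is strand-symmetric
})

test_that("sites too close to a chromosome end are dropped, not padded", {
  sites <- tiny_sites(c(200L, 10150L), chrom_length = 2e4)
  fr <- make_frags(10100L, 10200L)
  expect_warning(prof <- fragment_center_profile(fr, sites), "dropped")
  expect_equal(prof$n_sites, 1L)
  only_bad <- tiny_sites(300L, chrom_length = 2e4)
  expect_warning(expect_error(fragment_center_profile(fr, only_bad),
                              "no usable sites"))
})

test_that("uniform fragments give a flat profile", {
  set.seed(default_fixture_seed)
  # midpoints uniform over the whole window, ~1000 per bin
  starts <- sample(9450L:10449L, 100000L, replace = TRUE)
  fr <- make_frags(starts, starts + 100L)
  sites <- tiny_sites(10000L)
  prof <- fragment_center_profile(fr, sites)
  expect_lt(max(prof$signal) / min(prof$signal), 1.5)
})

test_that("binning agrees exactly with the brute-force double loop", {
  set.seed(default_fixture_seed)
  params <- profile_params()
  starts <- sample.int(30000L, 1000L, replace = TRUE)
  fr <- make_frags(starts, starts + sample(30:400, 1000L, replace = TRUE))
  sites <- tiny_sites(c(5000L, 5400L, 15000L, 25000L),
                      strand = c("+", "-", "-", "+"))
  prof <- fragment_center_profile(fr, sites, params)
  expect_equal(prof$signal, oracle_center_profile(fr, sites, params))
})

test_that("strand reversal leaves profiles of strand-symmetric input unchanged", {
  # fragments placed symmetrically around the anchor (counts(d) == counts(-d))
  offs <- c(-205, -185, -45, 45, 185, 205, 5, -5)
  fr <- make_frags(10000L + offs - 50L, 10000L + offs + 50L)
  p_plus <- fragment_center_profile(fr, tiny_sites(10000L, "+"))
  p_minus <- fragment_center_profile(fr, tiny_sites(10000L, "-"))
  expect_equal(p_plus$signal, p_minus$signal)
})

test_that("background normalization sets the first five bins to one", {
  p <- manual_profile(c(rep(2, 5), 4, rep(2, 94)))
  n <- normalize_background(p)
  expect_equal(n$signal[1:5], rep(1, 5))
  expect_equal(n$signal[6], 2)
  expect_equal(mean(n$signal[1:5]), 1, tolerance = 1e-12)
  expect_true(n$normalized)
  expect_equal(normalize_background(n), n)  # idempotent
  expect_error(normalize_background(manual_profile(rep(0, 100))),
               "zero mean")
})

test_that("reference transform recovers affine relations", {
  ref <- manual_profile(1 + sin(seq(0, 3 * pi, length.out = 100)))
  t_id <- fit_reference_transform(ref, ref)
  expect_equal(t_id$scale, 1)
  expect_equal(t_id$offset, 0)

  other <- manual_profile(2 * ref$signal + 1)
  t2 <- fit_reference_transform(ref, other)
  expect_equal(t2$scale, 0.5)
  expect_equal(t2$offset, -0.5)
  expect_equal(apply_transform(other, t2)$signal, ref$signal)

  # noisy affine relation: matches the closed-form simple regression
  set.seed(default_fixture_seed)
  noisy <- manual_profile(3 * ref$signal - 0.2 + rnorm(100, 0, 0.05))
  t3 <- fit_reference_transform(ref, noisy)
  x <- noisy$signal; y <- ref$signal
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(t3$scale, beta, tolerance = 1e-10)
  expect_equal(t3$offset, mean(y) - beta * mean(x), tolerance = 1e-10)
  expect_equal(t3$scale, 1 / 3, tolerance = 0.05)

  expect_error(fit_reference_transform(ref, manual_profile(rep(2, 100))),
               "constant")
})

test_that("spline smoothing preserves mass and damps noise", {
  const <- manual_profile(rep(3, 100))
  expect_equal(smooth_profile(const)$signal, rep(3, 100), tolerance = 1e-6)

  spike <- manual_profile(c(rep(1, 49), 10, rep(1, 50)))
  sm <- smooth_profile(spike)
  expect_lt(sm$signal[50], 10)                        # spike attenuated
  expect_gt(mean(sm$signal[c(49, 51)]), 1)            # neighbours raised
  expect_equal(sum(sm$signal), sum(spike$signal), tolerance = 0.05 * sum(spike$signal))

  set.seed(default_fixture_seed)
  x <- seq(0, 4 * pi, length.out = 100)
  clean <- 2 + sin(x)
  noisy <- manual_profile(clean + rnorm(100, 0, 0.3))
  sm2 <- smooth_profile(noisy)
  expect_lt(sd(sm2$signal - clean), sd(noisy$signal - clean))

  expect_error(smooth_profile(const, profile_params(smoothing_parameter = 1.5)),
               "smoothing_parameter")
})

test_that("summit localization finds flanking maxima with sub-bin refinement", {
  sym <- bump_profile(c(-185, 185))
  s <- locate_summits(sym)
  expect_lt(abs(s$left + 185), 5)
  expect_lt(abs(s$right - 185), 5)
  expect_equal(s$inter_summit_distance, s$right - s$left)

  asym <- bump_profile(c(-165, 205))
  s2 <- locate_summits(asym)
  expect_lt(abs(s2$left + 165), 5)
  expect_lt(abs(s2$right - 205), 5)

  mono_up <- manual_profile(seq(0, 1, length.out = 100), normalized = TRUE,
                            smoothed = TRUE)
  expect_error(locate_summits(mono_up), "local max")

  raw <- bump_profile(c(-185, 185)); raw$smoothed <- FALSE
  expect_error(locate_summits(raw), "smoothed")
})

test_that("compaction is the change in inter-summit distance", {
  ctrl <- bump_profile(c(-185, 185))
  pert <- bump_profile(c(-165, 165))
  res <- estimate_compaction(ctrl, pert)
  expect_equal(res$total_compaction, 40)
  expect_equal(unname(res$per_flank_shift), c(20, 20))

  same <- estimate_compaction(ctrl, ctrl)
  expect_equal(same$total_compaction, 0)

  pert25 <- bump_profile(c(-173, 172))
  res25 <- estimate_compaction(ctrl, pert25)
  expect_lt(abs(res25$total_compaction - 25), 2)
})

test_that("compaction is invariant to library depth when reference-scaled", {
  g <- genome_model("chrS", 8e6)
  p63 <- generate_sites(g, 300, "p63-like", min_spacing = 3000, seed = 31)
  ctcf <- generate_sites(g, 150, "CTCF-like", min_spacing = 3000, seed = 32)
  sites <- rbind(p63, ctcf)
  attr(sites, "chrom_length") <- attr(p63, "chrom_length")
  ctrl <- simulate_fragments(sites, condition_profile("CTRL"),
                             frags_per_site = 60, seed = 33)$fragments
  pert <- simulate_fragments(sites, condition_profile("BAFi"),
                             frags_per_site = 60, seed = 34)$fragments
  base <- run_compaction_analysis(ctrl, pert, p63, ctcf)
  tripled <- pert[rep(seq_len(nrow(pert)), 3L), ]
  scaled <- run_compaction_analysis(ctrl, tripled, p63, ctcf)
  expect_equal(scaled$total_compaction, base$total_compaction)
})

test_that("coverage metaplots are library-size normalized", {
  sites <- tiny_sites(10000L)
  one <- data.frame(chrom = "chrT", start = 10000L, end = 10001L,
                    name = "r1", score = 0, strand = "+",
                    stringsAsFactors = FALSE)
  prof <- coverage_metaplot(one, sites)
  expect_equal(prof$signal[51L], 1e6)  # 1 count / (1 read / 1e6)
  expect_equal(sum(prof$signal), 1e6)

  set.seed(default_fixture_seed)
  pos <- sample(9500L:10499L, 400L, replace = TRUE)
  reads <- data.frame(chrom = "chrT", start = pos, end = pos + 1L,
                      name = paste0("r", seq_along(pos)), score = 0,
                      strand = "+", stringsAsFactors = FALSE)
  p1 <- coverage_metaplot(reads, sites)
  doubled <- coverage_metaplot(reads[rep(seq_along(pos), 2L), ], sites)
  expect_equal(doubled$signal, p1$signal)  # duplication leaves profile fixed

  expect_error(coverage_metaplot(reads[0, ], sites), "no records")
})
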