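test_that("PRD matches its closed form", {
  x <- c(3, 4)
  expect_equal(prd(x, x), 0)
  expect_equal(prd(x, 1.1 * x), 10)
  expect_equal(prd(x, c(0, 0)), 100)  # sqrt(25/25) * 100
  set.seed(1)
  y <- rnorm(50)
  e <- rnorm(50)
  # linear in the error amplitude for a fixed reference
  expect_equal(prd(y, y + 2 * e), 2 * prd(y, y + e))
  expect_error(prd(y, y[-1]), "identical dimensions")
  expect_error(prd(rep(0, 5), rnorm(5)), "all-zero")
})

test_that("regional PRDs separate support and recombine to the global PRD", {
  rec <- fixture_record(seed = 12, duration_s = 6, n_leads = 2)
  x1 <- rec$ecg
  ann <- rec$annotations
  # perturb only out-of-wave samples
  n <- n_samples(x1)
  pos <- (seq_len(n)) - 1
  inwave <- rep(FALSE, n)
  for (i in seq_len(nrow(ann)))
    inwave <- inwave | (pos >= ann$p_on[i] & pos <= ann$t_end[i])
  x2 <- x1$signal
  x2[!inwave, ] <- x2[!inwave, ] + 10
  lp <- local_prd(x1, x2, ann)
  expect_equal(unname(lp$prd[c("P", "QRS", "T")]), c(0, 0, 0))
  expect_gt(lp$prd["out"], 0)

  # sum-of-squares recombination of the regional numerators
  nu <- encode_ecg(x1, annotations = ann)
  dec <- decode_ecg(nu)
  lp2 <- local_prd(x1, dec, ann)
  masks <- adaptecg:::region_masks(ann, n)
  nums <- vapply(names(masks), function(r) {
    m <- masks[[r]]
    (lp2$prd[r] / 100)^2 * sum(x1$signal[m, ]^2)
  }, 0)
  expect_equal(sum(nums), sum((x1$signal - dec$signal)^2),
               tolerance = 1e-9)
  expect_equal(sqrt(sum(nums) / sum(x1$signal^2)) * 100, prd(x1, dec),
               tolerance = 1e-9)
})

test_that("the 12-bit ADC grid over +/-5 mV is ~2.44 uV per unit", {
  rec <- fixture_record(seed = 2, duration_s = 2, n_leads = 1)
  expect_equal(rec$ecg$resolution_uv, 10000 / 4096)
  expect_equal(round(rec$ecg$resolution_uv, 2), 2.44)
  # all stored amplitudes sit on the grid
  expect_true(all(abs(rec$ecg$signal / rec$ecg$resolution_uv -
                        round(rec$ecg$signal / rec$ecg$resolution_uv)) < 1e-9))
})

test_that("compression ratio follows the stream accounting", {
  expect_equal(uniform_stream_bps(12, 500, 12), 72000)
  rec <- fixture_record(seed = 3, duration_s = 4)
  # identity sampling: M = N, CR = sr / (sr + q) regardless of length
  nu1 <- encode_ecg(rec$ecg, amrf = rep(1, n_samples(rec$ecg)))
  expect_equal(compression_ratio(rec$ecg, nu1), 144 / 150)  # 0.96 < 1
  # all-minimum relevance: every interval at the 9.875 ms cap
  nu0 <- encode_ecg(rec$ecg, amrf = rep(0, n_samples(rec$ecg)))
  m <- length(nu0$codes)
  expect_equal(compression_ratio(rec$ecg, nu0),
               (n_samples(rec$ecg) * 12 * 12) / (m * 12 * 12 + m * 6))
  # span mismatch is refused
  shorter <- uniform_ecg(rec$ecg$signal[1:1000, ], fs = 500)
  expect_error(compression_ratio(shorter, nu0), "span")
})

test_that("diagnostic features read off the generator's construction", {
  wp <- default_wave_params()
  wp["Q", "amp_uv"] <- -220   # well clear of the 10% peak-count threshold
  wp["S", "amp_uv"] <- -260
  rec <- generate_ecg(synth_config(duration_s = 6, n_leads = 2,
                                   wave_params = wp, seed = 4))
  feats <- extract_features_all(rec$ecg, rec$annotations)
  f <- feats[[3]]
  expect_equal(f$RR_int, 1000)  # 60 bpm
  b <- rec$annotations[3, ]
  expect_equal(f$QRS_dur, (b$qrs_end - b$qrs_on) / 500 * 1000)
  expect_equal(f$P_dur, (b$p_end - b$p_on) / 500 * 1000)
  expect_equal(f$QT_int, (b$t_end - b$qrs_on) / 500 * 1000)
  expect_equal(f$QRS_peaks_no, 3)           # Q, R, S
  expect_true(f$Q_wave_exist)
  expect_false(f$Delta_wave_exist)
  expect_equal(f$T_shape, "positive")
  expect_equal(f$P_shape, "positive")
  expect_gt(f$QRSp_amp, 0)
  expect_lt(f$QRSn_amp, 0)
  # identical beats give identical feature vectors
  f2 <- extract_features(rec$ecg, rec$annotations[3, ], rr_ms = 1000)
  expect_identical(unclass(f), unclass(f2))
  expect_error(extract_features(rec$ecg, c(10, 20, 30, 40, 1e6)),
               "outside")
})

test_that("WDD identities and single-feature sensitivities hold", {
  rec <- fixture_record(seed = 4, duration_s = 4, n_leads = 1)
  f <- extract_features_all(rec$ecg, rec$annotations)[[2]]
  expect_equal(wdd(f, f), 0)
  # one categorical mismatch with weight 3 against trace 29.1
  g <- f
  g$ST_shape <- "upsloping"
  expect_equal(wdd(f, g), 100 * 3 / 29.1, tolerance = 1e-12)
  expect_equal(wdd(f, g), wdd(g, f))  # symmetric
  h <- f
  h$Q_wave_exist <- !f$Q_wave_exist
  expect_equal(wdd(f, h), 100 * 0.5 / 29.1, tolerance = 1e-12)
})

test_that("stream estimate hits its floor, ceiling and monotonicity", {
  pol <- sampling_policy()
  lmk <- c(106, 196, 246, 338, 672)
  zero <- mrf_template(rep(0, 50), lmk)
  expect_equal(estimate_stream(zero, pol, sr = 12), 100 * 12)
  # bl * sum(MRF) = 1 -> d = fs * sr
  unit <- mrf_template(rep(1 / (0.032 * 50), 50), lmk)
  expect_equal(estimate_stream(unit, pol, sr = 12), 500 * 12)
  sums <- seq(0.1, 0.9, by = 0.2)
  d <- vapply(sums, function(s)
    estimate_stream(mrf_template(rep(s, 50), lmk), pol, 12), 0)
  expect_true(all(diff(d) > 0))
})

test_that("Beurling density estimate behaves on uniform and thinned grids", {
  times <- seq(0, 4, by = 0.002)
  expect_equal(beurling_density(times, 1), 500)
  thinned <- times[-seq(10, 1500, by = 7)]
  expect_lte(beurling_density(thinned, 1), 500)
  expect_error(beurling_density(times, 10), "window longer")
  expect_error(beurling_density(0.5, 1), "two samples")
})
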