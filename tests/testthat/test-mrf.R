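ref_landmarks <- c(106, 196, 246, 338, 672)

test_that("built-in templates carry the reference landmark set", {
  tpl <- default_gmrf()
  expect_equal(tpl$landmarks, ref_landmarks)
  expect_equal(smrf_qrs_roi()$landmarks, ref_landmarks)
  expect_equal(tpl$bin_length_s, 0.032)
  expect_true(all(tpl$values >= 0 & tpl$values <= 1))
  expect_equal(max(tpl$values), 1)
})

test_that("template I/O round-trips through JSON and CSV", {
  tpl <- default_gmrf()
  for (ext in c(".json", ".csv")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_mrf_template(tpl, tf)
    back <- read_mrf_template(tf)
    expect_equal(back$values, tpl$values)
    expect_equal(back$landmarks, tpl$landmarks)
    expect_equal(back$bin_length_s, tpl$bin_length_s)
  }
  # built-in names resolve too, and the packaged files match the code
  expect_equal(read_mrf_template("gmrf_default")$values, tpl$values)
  pkg_file <- system.file("extdata", "gmrf_default.json",
                          package = "adaptecg")
  expect_equal(read_mrf_template(pkg_file)$values, tpl$values)
})

test_that("template validation enforces the schema", {
  expect_error(mrf_template(c(0.2, 0.4), c(1, 2, 3, 4)), "five landmarks")
  expect_error(mrf_template(c(0.2, 0.4), c(1, 3, 2, 4, 5)), "increasing")
  expect_error(mrf_template(c(-0.1, 0.4), 1:5 * 3), "non-negative")
  expect_error(mrf_template(rep(0.5, 4), c(1, 2, 3, 4, 1000)), "support")
  # constant-1 template is accepted and stays all-ones
  flat <- mrf_template(rep(1, 10), c(10, 40, 60, 80, 150))
  expect_true(all(flat$values == 1))
})

test_that("identity-spaced annotations reproduce the template 1:1", {
  tpl <- default_gmrf()
  offset <- 100
  borders <- tpl$landmarks + offset  # same spacings as the landmarks
  pos <- seq(borders[1], borders[5], by = 1)
  got <- project_mrf(tpl, borders, pos, fs = 500)
  expect_equal(got, mrf_value(tpl, pos - offset))
})

test_that("landmark positions map exactly under arbitrary stretchings", {
  tpl <- default_gmrf()
  set.seed(2024)
  for (i in 1:100) {
    b <- random_annotation()
    got <- project_mrf(tpl, b, positions = as.numeric(b), fs = 500)
    expect_equal(got, mrf_value(tpl, tpl$landmarks), tolerance = 1e-12)
  }
})

test_that("a dilated segment matches a dense resampling oracle", {
  tpl <- default_gmrf()
  a <- tpl$landmarks
  # dilate the QRS-end..T-end segment by exactly 2
  b <- c(a[1:4], a[4] + 2 * (a[5] - a[4]))
  pos <- seq(b[4], b[5], length.out = 400)
  got <- project_mrf(tpl, b, pos, fs = 500)
  # independent oracle: dense linear interpolation of the template over the
  # stretched axis, built directly from bin centers
  spb <- tpl$bin_length_s * tpl$grid_fs
  centers <- (seq_along(tpl$values) - 0.5) * spb
  a_dense <- a[4] + (pos - b[4]) / 2
  oracle <- stats::approx(centers, tpl$values, xout = a_dense, rule = 2)$y
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("projection preserves segment extrema and relevance mass scaling", {
  tpl <- default_gmrf()
  a <- tpl$landmarks
  b2 <- c(a[1:4], a[4] + 2 * (a[5] - a[4]))
  for (k in 1:4) {
    ref_vals <- mrf_value(tpl, seq(a[k], a[k + 1], by = 0.25))
    pos <- seq(b2[k], b2[k + 1], length.out = 2000)
    got <- project_mrf(tpl, b2, pos, fs = 500)
    expect_lte(max(got), max(ref_vals) + 1e-9)
    expect_gte(min(got), min(ref_vals) - 1e-9)
  }
  # mass over the x2-dilated segment is twice the template segment mass
  pos <- seq(b2[4], b2[5], length.out = 4000)
  mass <- mean(project_mrf(tpl, b2, pos, fs = 500)) * (b2[5] - b2[4])
  apos <- seq(a[4], a[5], length.out = 4000)
  ref_mass <- mean(mrf_value(tpl, apos)) * (a[5] - a[4])
  expect_equal(mass, 2 * ref_mass, tolerance = 1e-3)
})

test_that("invalid annotations fall back to maximum relevance", {
  tpl <- default_gmrf()
  bad <- c(100, 90, 200, 300, 400)  # non-monotone
  expect_equal(project_mrf(tpl, bad, 0:10, fs = 500), rep(1, 11))
})

test_that("adapted MRF covers the record, holds its floor, and honours flags", {
  rec <- fixture_record(seed = 3, duration_s = 6)
  tpl <- default_gmrf()
  ann <- rec$annotations
  amrf <- adapt_mrf(tpl, ann, n_samples(rec$ecg), 500)
  expect_length(amrf, n_samples(rec$ecg))
  expect_true(all(amrf >= 0 & amrf <= 1))
  floor_val <- min(tpl$values[1], tpl$values[length(tpl$values)])
  expect_gte(min(amrf), floor_val)
  expect_equal(as.numeric(amrf[1]), floor_val)  # before the first beat
  # a flagged beat is coded at maximum relevance across its span
  ann$flagged[3] <- TRUE
  amrf2 <- adapt_mrf(tpl, ann, n_samples(rec$ecg), 500)
  span <- (floor(ann$p_on[3]) + 2):(ceiling(ann$t_end[3]))
  expect_true(all(amrf2[span] == 1))
})
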