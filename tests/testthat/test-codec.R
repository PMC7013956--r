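test_that("interval law and quantizer reproduce the reference arithmetic", {
  pol <- sampling_policy(fs = 500, fm = 100, quant_bits = 6)
  expect_equal(pol$P, 64L)
  expect_equal(pol$step * 1000, 0.125)  # ms
  expect_equal(sampling_policy(500, 50)$step * 1000, 0.28125)

  # maximum relevance samples at the native interval, code 0
  expect_equal(ls_from_relevance(1, pol), 0.002)
  expect_equal(code_from_ls(ls_from_relevance(1, pol), pol), 0L)
  # relevance 0.5 -> 6 ms -> code 32 (6 = 2 + 32 * 0.125)
  expect_equal(ls_from_relevance(0.5, pol), 0.006)
  expect_equal(code_from_ls(0.006, pol), 32L)
  expect_equal(ls_from_code(32L, pol), 0.006)
  # largest representable interval is Ts + 63 steps
  expect_equal(ls_from_code(pol$P - 1L, pol), 0.002 + 63 * 0.000125)

  expect_error(sampling_policy(fs = 500, fm = 600), "fm < fs")
})

test_that("larger relevance never yields a longer interval", {
  pol <- sampling_policy()
  r <- seq(0, 1, length.out = 201)
  ls <- ls_from_relevance(r, pol)
  expect_true(all(diff(ls) <= 0))
  expect_true(all(diff(code_from_ls(ls, pol)) <= 0))
})

test_that("the interval walk emits a decodable schedule on the code grid", {
  pol <- sampling_policy()
  amrf <- rep(0.5, 1000)
  sched <- intervals_from_mrf(amrf, pol)
  expect_true(all(sched$code == 32L))
  expect_equal(diff(sched$time), rep(0.006, nrow(sched) - 1))
  # times are exactly recoverable from the codes
  expect_equal(sched$time,
               cumsum(c(0, ls_from_code(sched$code[-nrow(sched)], pol))))
  expect_error(intervals_from_mrf(numeric(0), pol), "empty")
})

test_that("anti-alias filtering is transparent for DC and at the native rate", {
  pol <- sampling_policy()
  dc <- uniform_ecg(matrix(250, 800, 2), fs = 500)
  for (code in c(0L, 16L, 63L)) {
    out <- antialias(dc, rep(code, 800), pol)
    expect_lt(max(abs(out$signal - 250)) / 250, 0.01)
  }
  rec <- fixture_record(seed = 2, duration_s = 3, n_leads = 2)
  thru <- antialias(rec$ecg, rep(0L, n_samples(rec$ecg)), pol)
  expect_lt(max(abs(thru$signal - rec$ecg$signal)) /
              diff(range(rec$ecg$signal)), 0.01)
})

test_that("anti-alias kernels attenuate one octave above cutoff by >= 4 dB", {
  pol <- sampling_policy()
  for (code in c(8L, 32L, 63L)) {
    h <- adaptecg:::aa_kernel(code, pol)
    fc <- 0.45 / ls_from_code(code, pol)
    H <- function(f) abs(sum(h * exp(-2i * pi * f * (0:10) / pol$fs)))
    expect_equal(H(0), 1, tolerance = 1e-9)       # unity DC gain
    expect_lt(20 * log10(H(2 * fc) / H(0)), -4)   # gentle low-pass slope
  }
})

test_that("encoder contracts: shared stream, fewer samples, identity path", {
  rec <- fixture_record(seed = 5)
  nu <- encode_ecg(rec$ecg, annotations = rec$annotations)
  expect_lt(length(nu$codes), n_samples(rec$ecg))
  expect_equal(ncol(nu$values), 12)         # every lead at the shared times
  expect_equal(nrow(nu$values), length(nu$codes))
  expect_true(all(nu$codes >= 0 & nu$codes <= 63))

  # relevance forced to 1 everywhere reproduces the input on its native grid
  nu1 <- encode_ecg(rec$ecg, amrf = rep(1, n_samples(rec$ecg)))
  expect_equal(length(nu1$codes), n_samples(rec$ecg))
  expect_equal(nuecg_values_uv(nu1), unname(rec$ecg$signal))
})

test_that("a record with no detectable beats is coded at maximum relevance", {
  noise <- uniform_ecg(matrix(0, 1500, 2), fs = 500)
  expect_warning(nu <- encode_ecg(noise), "maximum relevance")
  expect_true(all(nu$codes == 0L))
})

test_that("cubic polynomials survive encode/decode exactly", {
  fs <- 500
  t <- (0:2499) / fs
  x <- 1000 * (3 + 2 * t - 0.8 * t^2 + 0.12 * t^3)
  ecg <- uniform_ecg(x, fs)  # resolution NA: exact amplitudes
  amrf <- 0.5 + 0.5 * sin(2 * pi * 0.7 * t)^2  # varied interval pattern
  dec <- decode_ecg(encode_ecg(ecg, amrf = amrf))
  expect_equal(n_samples(dec), n_samples(ecg))
  expect_equal(dec$fs, fs)
  expect_lt(max(abs(dec$signal - ecg$signal)) / diff(range(x)), 1e-6)
})

test_that("a 5 Hz tone round-trips below 1% PRD at the coarsest sampling", {
  tone <- generate_bandlimited(5, fs = 500, duration_s = 10)
  nu <- encode_ecg(tone, amrf = rep(0, n_samples(tone)))
  expect_true(all(nu$codes == 63L))  # longest representable interval
  expect_lt(prd(tone, decode_ecg(nu)), 1)
})

test_that("round trips preserve length and rate on synthetic records", {
  rec <- fixture_record(seed = 7, duration_s = 5, n_leads = 3)
  nu <- encode_ecg(rec$ecg, annotations = rec$annotations)
  dec <- decode_ecg(nu)
  expect_equal(n_samples(dec), n_samples(rec$ecg))
  expect_equal(dec$fs, rec$ecg$fs)
  expect_equal(dec$lead_labels, rec$ecg$lead_labels)
})

test_that("the NUECG container round-trips bit-exactly", {
  rec <- fixture_record(seed = 1, duration_s = 4, n_leads = 3)
  nu <- encode_ecg(rec$ecg, annotations = rec$annotations)
  tf <- withr::local_tempfile(fileext = ".nuecg")
  write_nuecg(nu, tf)
  back <- read_nuecg(tf)
  for (f in c("codes", "values", "lead_labels", "bit_depth",
              "value_format", "resolution_uv", "n_samples_uniform"))
    expect_equal(back[[f]], nu[[f]], info = f)
  expect_equal(back$policy, nu$policy)

  # payload accounting: M*q code bits + M*L*sr value bits
  m <- length(nu$codes)
  expect_equal(nuecg_payload_bits(nu), m * 6 + m * 3 * 12)
  # file payload equals the bit counts rounded up to byte boundaries
  header <- 6 + 2 + 2 + 16 + 2 + 8 + 8 + sum(nchar(nu$lead_labels) + 1)
  expect_equal(file.info(tf)$size - header,
               ceiling(m * 6 / 8) + ceiling(m * 3 * 12 / 8))
})

test_that("corrupt NUECG files raise format errors", {
  rec <- fixture_record(seed = 1, duration_s = 3, n_leads = 2)
  nu <- encode_ecg(rec$ecg, annotations = rec$annotations)
  tf <- withr::local_tempfile(fileext = ".nuecg")
  write_nuecg(nu, tf)
  raw <- readBin(tf, "raw", file.info(tf)$size)

  truncated <- withr::local_tempfile()
  writeBin(raw[seq_len(length(raw) - 50)], truncated)
  expect_error(read_nuecg(truncated), "truncated")

  bad <- raw; bad[2] <- as.raw(88)
  badf <- withr::local_tempfile()
  writeBin(bad, badf)
  expect_error(read_nuecg(badf), "magic")
})

test_that("float-valued records survive the container exactly", {
  tone <- generate_bandlimited(c(3, 7), fs = 500, duration_s = 3)
  nu <- encode_ecg(tone, amrf = rep(0.3, n_samples(tone)))
  expect_equal(nu$value_format, "float")
  tf <- withr::local_tempfile(fileext = ".nuecg")
  write_nuecg(nu, tf)
  expect_identical(read_nuecg(tf)$values, nu$values)
})
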