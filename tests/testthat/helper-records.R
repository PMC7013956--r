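# shared fixtures, generated in code at test time

fixture_record <- function(seed = 3, duration_s = 10, bpm = 60,
                           n_leads = 12, noise = 5) {
  generate_ecg(synth_config(heart_rate_bpm = bpm, duration_s = duration_s,
                            fs = 500, n_leads = n_leads,
                            noise_rms_uv = noise, seed = seed))
}

# a valid random annotation for property tests: five strictly increasing
# borders with wave-like spacings, inside [0, n_max)
random_annotation <- function(n_max = 5000) {
  start <- runif(1, 10, n_max - 600)
  gaps <- c(runif(1, 20, 80),   # P duration
            runif(1, 10, 60),   # PQ segment
            runif(1, 30, 80),   # QRS duration
            runif(1, 100, 260)) # QRS-end to T-end
  b <- start + cumsum(c(0, gaps))
  names(b) <- c("p_on", "p_end", "qrs_on", "qrs_end", "t_end")
  b
}
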