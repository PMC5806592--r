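# Shared fixture builders. Everything is generated in code at test time; no
# binary fixtures are stored.

# quick eeg_epochs wrapper around a bare matrix (already conditioned data)
epochs_from_matrix <- function(m, fs) {
  structure(
    list(data = m, fs = fs, epoch_dur = ncol(m) / fs,
         rejection_mask = matrix(FALSE, nrow(m), ncol(m)),
         n_rejected = integer(nrow(m)), g_r = rep(1, nrow(m)),
         usable = rep(TRUE, nrow(m)), g_r_applied = TRUE),
    class = "eeg_epochs"
  )
}

# a quiet low-noise simulation truth for deterministic-ish pipeline tests
quiet_truth <- function(seed, noise = 0, ...) {
  args <- utils::modifyList(
    list(noise_rms_uV = noise, line_amps_uV = c(`60` = 0),
         excursion_rate_per_min = 0, seed = seed),
    list(...))
  do.call(simulation_truth, args)
}

expect_rms_lt <- function(x, bound) {
  expect_lt(sqrt(mean(x^2)), bound)
}
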