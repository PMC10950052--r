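# Shared fixtures, built in code at test time.

# balanced 2x2 design: one row per trial
make_design <- function(trials_per_cell) {
  des <- tidyr::expand_grid(pu = c("low", "high"), au = c("low", "high"),
                            rep = seq_len(trials_per_cell))
  des$n_options <- ifelse(des$au == "low", 1L, 3L)
  des$rep <- NULL
  des
}

# reference generating parameters used across LBA tests
ref_params <- function() {
  lba_parameters(v = c(3.5, 2.5, 3.0, 2.0), b = 1.2, z = 0.6, t0 = 0.35)
}

ref_trials <- function(trials_per_cell = 150, seed = 7) {
  simulate_lba(ref_params(), make_design(trials_per_cell), seed = seed)
}

# tiny cohort with envelopes, for latency-pipeline tests
small_cohort <- function(n_subjects = 3, trials_per_cell = 30, n_roi = 4,
                         snr = 4, seed = 11, ...) {
  spec <- cohort_spec(n_controls = n_subjects, n_patients = 0,
                      trials_per_cell = trials_per_cell, n_roi = n_roi,
                      n_dorsal = n_roi, snr = snr, seed = seed, ...)
  beh <- generate_cohort_behaviour(spec)
  list(spec = spec, behaviour = beh,
       envelopes = generate_envelopes(spec, beh))
}
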