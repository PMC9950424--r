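# Degenerate posterior from a cohort's own generating parameters: isolates
# the forecasting machinery from MCMC estimation error (initial states are
# still re-estimated per subject from windowed data).
truth_fit <- function(cohort, ndraws = 100) {
  adpm_fixed_fit(cohort, ndraws = ndraws)
}
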