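# Shared fixtures: a wild-type-like trimer model with the measured level
# conductances, and the standard symmetric / bi-ionic solutions.

wt_model <- function(k_open = 8, k_close = 8) {
  gating_model(n_monomers = 3, k_open = k_open, k_close = k_close,
               level_conductances = c(0, 42.2, 100.6, 163.7))
}

sym_k_conditions <- function() {
  ion_conditions(pipette = c(K = 210, Cl = 210),
                 bath = c(K = 210, Cl = 210),
                 permeabilities = c(K = 1))
}

# Level mean currents (pA) at +60 mV with E_rev = 0 for the wild-type model
wt_level_means <- c(0, 2.532, 6.036, 9.822)
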