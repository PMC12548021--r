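# shared fixtures built in code

application_data <- function(...) {
  assemble_observed(covid_schizophrenia(...), apply = "never")
}

# a small, well-behaved synthetic meta-analysis with an error-prone covariate
synthetic_trivariate <- function(n = 12, seed = 42) {
  set.seed(seed)
  d <- generate_scenario(sim_config(2, n_studies = n, tau2 = 0.3, seed = seed))
  d
}
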