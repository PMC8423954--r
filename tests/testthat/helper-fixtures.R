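# Small cohort configurations used across tests.

null_specs <- function(n_features = 6) {
  specs <- default_feature_specs()[seq_len(n_features), ]
  specs$d_genotype <- 0
  specs$d_treatment <- 0
  specs$d_wt_treatment <- 0
  specs
}

null_config <- function(seed = 1, n = 13, n_features = 6, rho = 0) {
  cohort_config(
    group_sizes = c("WT-Veh" = n, "WT-C31" = 4, "R6/2-Veh" = n, "R6/2-C31" = 4),
    features = null_specs(n_features), correlation_rho = rho, seed = seed)
}

quiet_generate <- function(config) {
  suppressWarnings(generate_cohort(config))
}
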