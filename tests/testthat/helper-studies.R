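# Replicated studies are expensive, so the acceptance tests share them
# through a per-session cache. Study conditions (400 genes per replicate,
# the preset parameter blocks, true-partition / true-value initialization)
# are fixed; only the replicate count is reduced to desk scale.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(preset, n_replicates = 30L, seed = 20240601L,
                         fit_baseline = TRUE, fit_kmeans = FALSE) {
  key <- paste(preset, n_replicates, seed, fit_baseline, fit_kmeans,
               sep = "_")
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- replicate_study(
      preset, n_replicates = n_replicates, seed = seed,
      fit_baseline = fit_baseline, fit_kmeans = fit_kmeans)
  }
  .study_cache[[key]]
}

study_mean <- function(study, method, metric = "error_rate") {
  s <- study$summary
  s[s$metric == metric & s$method == method, "mean"]
}
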