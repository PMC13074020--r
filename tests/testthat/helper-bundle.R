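# one trained avatar bundle shared across modeling/interpretability/reporting
bundleFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generateCohort(tinyCohortConfig(n = 350, seed = 51))
      st <- pipelineDefaults()
      st$seed <- 51; st$topK <- 10
      fit <- trainAvatar(sim$cohort, st)
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})
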