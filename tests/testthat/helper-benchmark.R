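# The synthetic evaluation benchmark: 30 classes (two small held-out
# indicators), 20,000 objects in 32 dimensions, centroid separation >= 10
# within-class sigma, 2% uniform background noise, oracle annotator at the
# default 0.9 purity threshold, schedule 128 -> 4, generator seed 0.
# Computed once per test session and shared across test files.
benchmark_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_dataset(synth_config(rng_seed = 0))
      ann <- oracle_annotator(d$labels)
      run <- run_full(d$features, ann)
      recovery <- recovery_report(run, d$labels, d$indicator_classes)
      cache <<- list(data = d, annotator = ann, run = run, recovery = recovery)
    }
    cache
  }
})
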