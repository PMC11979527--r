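# The benchmark run is expensive (2e5 reports); generate it once per test
# session and share it across test files.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_run <- function() {
  if (is.null(.benchmark_cache$res)) {
    cfg <- benchmark_default()
    .benchmark_cache$cfg <- cfg
    .benchmark_cache$res <- run_pipeline(
      config = cfg,
      reference = benchmark_reference(cfg),
      annotations = benchmark_annotations(cfg)
    )
  }
  .benchmark_cache$res
}

benchmark_cfg <- function() {
  invisible(benchmark_run())
  .benchmark_cache$cfg
}

pair_id <- function(d1, d2) paste(pmin(d1, d2), pmax(d1, d2), sep = " + ")

benchmark_pairs_by_label <- function(pattern) {
  cfg <- benchmark_cfg()
  p <- cfg$pairs[grepl(pattern, cfg$pairs$label)]
  pair_id(p$drug1, p$drug2)
}
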