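# Shared fixtures. The default synthetic pipeline run is computed once per
# test session and reused by the network-level tests.

.fixture_env <- new.env(parent = emptyenv())

default_pipeline_run <- function(seed = 1L) {
  key <- paste0("run_", seed)
  if (!exists(key, envir = .fixture_env)) {
    out_dir <- file.path(tempdir(), paste0("florinet_run_", seed))
    cfg <- pipeline_config(out_dir = out_dir,
                           simulate = synthetic_config(seed = seed))
    report <- run_pipeline(cfg)
    assign(key, list(config = cfg, report = report, out_dir = out_dir,
                     dataset = simulate_dataset(synthetic_config(seed = seed))),
           envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

random_motif <- function(width, concentration = 1) {
  m <- matrix(rgamma(width * 4L, shape = concentration), ncol = 4L)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  motif_model(sprintf("rnd_w%d_%d", width, sample.int(1e6, 1L)), m)
}

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
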