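# Shared test utilities.

# Error-free shotgun reads from a raw template string, both strands.
reads_from_template <- function(template, coverage, read_length = 100) {
  n <- round(coverage * nchar(template) / read_length)
  starts <- sample.int(nchar(template) - read_length + 1L, n, replace = TRUE)
  r <- substring(template, starts, starts + read_length - 1L)
  minus <- stats::runif(n) < 0.5
  if (any(minus)) r[minus] <- revcomp(r[minus])
  r
}

# Random DNA string of length n (uniform bases).
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A reduced run configuration that exercises every stage quickly.
small_run_config <- function(seed = 1) {
  cfg <- default_run_config(seed)
  cfg$karyotype$retained_length <- 50000L
  cfg$reads$coverage <- 8
  cfg$reads$error_rate <- 0
  cfg
}

# The reduced full run is the most expensive fixture. Share two independent
# run_all() invocations of the same config across test files: "first" for
# result checks, "second" only for determinism comparisons against "first".
.elimrep_test_cache <- new.env(parent = emptyenv())
cached_small_run <- function(which = c("first", "second"), seed = 5) {
  which <- match.arg(which)
  key <- paste0(which, "_", seed)
  if (!exists(key, envir = .elimrep_test_cache, inherits = FALSE)) {
    assign(key, run_all(small_run_config(seed)),
           envir = .elimrep_test_cache)
  }
  get(key, envir = .elimrep_test_cache, inherits = FALSE)
}
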