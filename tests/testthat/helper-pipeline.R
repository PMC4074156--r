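# Shared expensive fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

demo_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_dataset(default_config(), seed = 42)
  .fixture_env$ds
}

demo_run <- function() {
  if (is.null(.fixture_env$run)) {
    ds <- demo_dataset()
    .fixture_env$run <- run_all(ds$genome, ds$references, pipeline_config())
  }
  .fixture_env$run
}

# a random amino-acid string over the canonical alphabet
rand_protein <- function(n, seed = NULL) {
  draw <- function() paste(sample(rscout:::AA20, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# helper: brute-force maximum chain score over all hit subsets
brute_force_chain <- function(h, params = chain_params()) {
  n <- nrow(h)
  best <- 0
  cs <- ifelse(h$strand == "+", h$g_start, -h$g_end)
  ce <- ifelse(h$strand == "+", h$g_end, -h$g_start)
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(unique(h$strand[idx])) > 1L) next
    idx <- idx[order(cs[idx])]
    ok <- TRUE
    if (length(idx) > 1L) for (k in 2:length(idx)) {
      i <- idx[k - 1]; j <- idx[k]
      gap <- cs[j] - ce[i]
      if (!(cs[j] > cs[i] && gap <= params$max_intron &&
            gap >= -3 * params$max_query_overlap &&
            h$q_start[j] > h$q_start[i] && h$q_end[j] > h$q_end[i] &&
            h$q_end[i] - h$q_start[j] + 1 <= params$max_query_overlap)) {
        ok <- FALSE; break
      }
    }
    if (ok) best <- max(best, sum(h$score[idx]))
  }
  best
}

random_hits <- function(n, seed) {
  withr::with_seed(seed, {
    g <- sort(sample.int(30000, n))
    data.frame(
      scaffold_id = "s", strand = sample(c("+", "-"), n, replace = TRUE),
      frame = 0L, g_start = g, g_end = g + 3L * sample(20:80, n, replace = TRUE),
      query_id = "q",
      q_start = sample.int(300, n), q_end = 0L,
      s_start = 1L, s_end = 1L,
      score = sample(60:400, n, replace = TRUE), n_ident = 10L,
      qseq = "", sseq = "", stringsAsFactors = FALSE)
  })
}
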