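## Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function(seed = 1) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_scenario("small", seed = seed)
  }
  .fixture_env[[key]]
}

paper_dataset <- function(seed = 42) {
  key <- paste0("paper_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_scenario("paper_scale", seed = seed)
  }
  .fixture_env[[key]]
}

paper_pipeline <- function(seed = 42) {
  key <- paste0("pipe_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      run_regulon_pipeline(paper_dataset(seed), run_motif = FALSE)
  }
  .fixture_env[[key]]
}

## does each letter of an IUPAC consensus share a base with the target?
iupac_compatible <- function(consensus, target) {
  stopifnot(nchar(consensus) == nchar(target))
  all(vapply(seq_len(nchar(target)), function(i) {
    length(intersect(iupac_bases(substr(consensus, i, i)),
                     iupac_bases(substr(target, i, i)))) > 0
  }, logical(1)))
}

## a minimal hand-built two-condition count table
toy_counts <- function(counts, lengths = rep(1000, nrow(counts)),
                       n_rep = 2) {
  colnames(counts) <- c(paste0("WT_", seq_len(n_rep)),
                        paste0("KO_", seq_len(n_rep)))
  rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  count_table(counts, condition = rep(c("WT", "KO"), each = n_rep),
              gene_length = lengths)
}
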