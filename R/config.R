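#' Default run configuration
#'
#' A `RunConfig` collects every tunable threshold of the pipeline in one
#' nested list so a whole run is reproducible from a single flat text file
#' plus a seed.  Defaults are the values used throughout the documentation:
#'
#' * `peaks`: candidate-border threshold `k` (multiples of the local
#'   background), background window (bp), maximum border-pairing span (bp),
#'   local-maximum half-width (bp) and the minimum signal-to-noise ratio
#'   `sn_min` kept after reproducibility filtering.
#' * `motif`: motif width (bp), flank added around peaks before motif
#'   discovery (bp), number of EM restarts, iteration cap, Dirichlet
#'   pseudocount per base and per-sequence occurrence prior.
#' * `de`: minimum absolute log2 fold change and maximum BH q-value for a
#'   gene to be called differentially expressed.
#' * `tss_window`: strand-aware window around a TU's transcription start
#'   site (negative = upstream) within which a peak center is assigned to
#'   that TU.
#' * `chipexo` / `rnaseq` / `genome`: synthetic-data generator settings.
#'
#' @return a `RunConfig` object (a classed nested list).
#' @seealso [read_config()], [write_config()]
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    genome = list(length = 500000L, n_genes = 600L, n_tus = 350L),
    chipexo = list(depth = 500000L, noise = 0.05, mock_artifacts = 2L,
                   footprint = 30L, jitter = 2L, mock_background = 0.9),
    rnaseq = list(mean_count = 400, dispersion = 0.01,
                  samples_per_condition = 2L),
    peaks = list(k = 3, bg_window = 2000L, max_span = 100L,
                 local_halfwidth = 20L, sn_min = 1.0),
    motif = list(width = 10L, flank = 10L, restarts = 20L, max_iter = 200L,
                 pseudocount = 0.25, prior = 0.9),
    de = list(lfc_min = 1.0, fdr_max = 0.01, pseudocount = 1.0),
    tss_window = list(upstream = -500L, downstream = 200L)
  ), class = "RunConfig")
}

#' Write a run configuration as a flat key-value text file
#'
#' Nested names are flattened with dots (`peaks.k: 3`), one key per line,
#' YAML-parseable.
#'
#' @param config a `RunConfig`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  flat <- unlist(config)
  lines <- sprintf("%s: %s", names(flat), vapply(flat, format, "",
                                                 scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_config()]
#'
#' Unknown keys are rejected so a typo in a threshold name cannot silently
#' fall back to a default.  Missing keys keep their default values.
#'
#' @param path flat key-value config file.
#' @return a `RunConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  defaults <- default_config()
  flat_def <- unlist(defaults)
  unknown <- setdiff(names(raw), names(flat_def))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (key in names(raw)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    value <- raw[[key]]
    mode_def <- storage.mode(flat_def[[key]])
    storage.mode(value) <- if (mode_def == "integer") "integer" else "double"
    if (length(parts) == 1L) {
      cfg[[parts]] <- value
    } else {
      cfg[[parts[1]]][[parts[2]]] <- value
    }
  }
  cfg
}
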