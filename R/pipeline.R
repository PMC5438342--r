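#' Run the full regulon-reconstruction pipeline on a dataset
#'
#' Chains every stage: depth normalization of the six border profiles,
#' candidate peak calling per replicate and on the mock-IP track,
#' replicate-reproducibility intersection, signal-to-noise and mock
#' filtering, motif discovery on the surviving peak sequences,
#' differential-expression calling, regulon integration and the
#' known-site benchmark.  Mock peaks used for subtraction are themselves
#' required to pass the S/N threshold, so only genuine mock signal (not
#' sparse mock background) blacklists positions.
#'
#' @param dataset a [generate_scenario()] result, or any list with
#'   `profiles`, `genome`, `annotation`, `counts` and optionally
#'   `truth$known_sites`.
#' @param config a [default_config()] style `RunConfig`.
#' @param run_motif set `FALSE` to skip the (comparatively slow) motif
#'   stage.
#' @return list with `peaks`, `motif` (or `NULL`), `de`, `regulon`,
#'   `benchmark` and `config`.
#' @export
run_regulon_pipeline <- function(dataset, config = default_config(),
                                 run_motif = TRUE) {
  pk <- config$peaks
  prof <- lapply(dataset$profiles, normalize_depth)
  call_one <- function(fwd, rev) {
    call_candidate_peaks(fwd, rev, k = pk$k, bg_window = pk$bg_window,
                         max_span = pk$max_span,
                         local_halfwidth = pk$local_halfwidth)
  }
  cand1 <- call_one(prof$rep1_fwd, prof$rep1_rev)
  cand2 <- call_one(prof$rep2_fwd, prof$rep2_rev)
  mock <- call_one(prof$mock_fwd, prof$mock_rev)
  mock <- filter_peaks(mock, NULL, sn_min = pk$sn_min)
  merged <- reproducible_peaks(cand1, cand2)
  peaks <- filter_peaks(merged, mock, sn_min = pk$sn_min)
  re_log("pipeline: %d/%d replicate candidates -> %d reproducible -> %d final",
         nrow(cand1), nrow(cand2), nrow(merged), nrow(peaks))

  motif <- NULL
  if (run_motif && nrow(peaks) >= 2) {
    mo <- config$motif
    seqs <- extract_peak_sequences(peaks, dataset$genome,
                                   flank = mo$flank)
    motif <- discover_motif(seqs, width = mo$width,
                            restarts = mo$restarts,
                            max_iter = mo$max_iter, seed = config$seed,
                            prior = mo$prior,
                            pseudocount = mo$pseudocount)
  }

  de <- run_diffexpr(dataset$counts, lfc_min = config$de$lfc_min,
                     fdr_max = config$de$fdr_max,
                     pseudocount = config$de$pseudocount)
  window <- c(config$tss_window$upstream, config$tss_window$downstream)
  regulon <- build_regulon(peaks, dataset$annotation, de,
                           window = window)
  benchmark <- NULL
  if (!is.null(dataset$truth$known_sites)) {
    benchmark <- benchmark_known_sites(peaks, dataset$truth$known_sites)
  }
  list(peaks = peaks, motif = motif, de = de, regulon = regulon,
       benchmark = benchmark, config = config)
}
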