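#' Signed distance from a peak center to a transcription start site
#'
#' Strand-aware: on the plus strand `center - tss`, on the minus strand
#' `tss - center`; negative values are upstream of the TSS.
#'
#' @param center peak center position(s), 0-based.
#' @param tss TSS position(s), 0-based.
#' @param strand `"+"` or `"-"` (vectorized).
#' @return signed distance(s) in bp.
#' @export
distance_to_tss <- function(center, tss, strand) {
  ifelse(strand == "+", center - tss, tss - center)
}

#' Classify a binding location relative to the TSS
#'
#' Bins: distance below -100 is `upstream`, -100 to 0 is `promoter`,
#' above 0 is `five_prime` (5'-proximal to the coding region).  The -100
#' boundary is a documented package convention; moving it relabels
#' locations but never changes regulon membership.
#'
#' @param distance signed distance(s) from [distance_to_tss()].
#' @return character vector of location classes.
#' @export
classify_location <- function(distance) {
  ifelse(distance < -100, "upstream",
         ifelse(distance <= 0, "promoter", "five_prime"))
}

#' Assign peaks to transcription units by TSS window
#'
#' A peak is assigned to every TU whose strand-aware window around the TSS
#' (default -500 bp upstream to +200 bp downstream) contains the peak
#' center, so a peak between divergent promoters can legitimately map to
#' two TUs.  Peaks matching no TU are reported in the `unassigned`
#' attribute.
#'
#' @param peaks peak data.frame with `peak_id` and `center`.
#' @param annotation a [genome_annotation()].
#' @param window length-2 numeric, `c(upstream, downstream)` with upstream
#'   negative.
#' @return data.frame of assignments: `peak_id`, `tu_id`, `distance`,
#'   `location`; attribute `unassigned` holds unmatched peak ids.
#' @export
assign_peaks_to_tus <- function(peaks, annotation, window = c(-500, 200)) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  if (window[1] > window[2]) stop("window must be c(upstream, downstream)")
  tus <- annotation$tus
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    d <- distance_to_tss(peaks$center[i], tus$tss, tus$strand)
    hit <- which(d >= window[1] & d <= window[2])
    if (length(hit) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[i], tu_id = tus$tu_id[hit],
        distance = d[hit], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) {
    do.call(rbind, out)
  } else {
    data.frame(peak_id = character(0), tu_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  }
  res$location <- classify_location(res$distance)
  attr(res, "unassigned") <- setdiff(peaks$peak_id, res$peak_id)
  res
}

#' Causal mode of a bound transcription unit
#'
#' Given the differential-expression results of the TU's member genes:
#' if no member is significant the mode is `not_determined` (bound without
#' an expression response); if all significant members have
#' `log2FC(KO/WT) <= -1` the TF activated them (`activated`); if all have
#' `log2FC >= +1` it repressed them (`repressed`); mixed signs are flagged
#' `conflict` rather than coerced, since a genuine mixed TU would indicate
#' a caller or annotation problem worth surfacing.
#'
#' @param gene_ids member gene ids of one TU.
#' @param de_results data.frame from [run_diffexpr()] covering those
#'   genes.
#' @return one of `"activated"`, `"repressed"`, `"not_determined"`,
#'   `"conflict"`.
#' @export
classify_mode <- function(gene_ids, de_results) {
  de <- de_results[match(gene_ids, de_results$gene_id), , drop = FALSE]
  if (anyNA(de$gene_id)) stop("DE results do not cover all member genes")
  sig <- de[de$significant, , drop = FALSE]
  if (nrow(sig) == 0) return("not_determined")
  if (all(sig$log2fc <= 0)) return("activated")
  if (all(sig$log2fc >= 0)) return("repressed")
  "conflict"
}

#' Build the causally classified regulon
#'
#' Combines the filtered peak set, the genome annotation and the
#' differential-expression table into one regulon entry per bound TU, plus
#' the summary counts that describe the reconstruction: number of peaks,
#' bound TUs, distinct regulon genes, genes per causal mode, and directly
#' regulated genes (activated + repressed) with their TU count.  A gene is
#' counted once even when its TU carries several peaks.
#'
#' @param peaks filtered peak data.frame.
#' @param annotation a [genome_annotation()].
#' @param de_results data.frame from [run_diffexpr()].
#' @param window TSS window passed to [assign_peaks_to_tus()].
#' @return list with `entries` (data.frame: `tu_id`, `gene_ids`
#'   (comma-joined), `peak_ids`, `distance` (nearest peak), `location`,
#'   `mode`), `genes` (per-gene data.frame with mode and DE values) and
#'   `summary` (named list of counts).
#' @export
build_regulon <- function(peaks, annotation, de_results,
                          window = c(-500, 200)) {
  asn <- assign_peaks_to_tus(peaks, annotation, window = window)
  genes <- annotation$genes
  tu_ids <- unique(asn$tu_id)
  entries <- lapply(tu_ids, function(tu) {
    rows <- asn[asn$tu_id == tu, , drop = FALSE]
    members <- genes$gene_id[genes$tu_id == tu]
    mode <- classify_mode(members, de_results)
    nearest <- which.min(abs(rows$distance))
    data.frame(tu_id = tu,
               gene_ids = paste(members, collapse = ","),
               peak_ids = paste(rows$peak_id, collapse = ","),
               distance = rows$distance[nearest],
               location = rows$location[nearest],
               mode = mode, n_genes = length(members),
               stringsAsFactors = FALSE)
  })
  entries <- if (length(entries) > 0) do.call(rbind, entries) else
    data.frame(tu_id = character(0), gene_ids = character(0),
               peak_ids = character(0), distance = numeric(0),
               location = character(0), mode = character(0),
               n_genes = integer(0), stringsAsFactors = FALSE)
  gene_rows <- if (nrow(entries) > 0) {
    do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
      ids <- strsplit(entries$gene_ids[i], ",")[[1]]
      de <- de_results[match(ids, de_results$gene_id), , drop = FALSE]
      data.frame(gene_id = ids, tu_id = entries$tu_id[i],
                 mode = entries$mode[i], log2fc = de$log2fc,
                 qvalue = de$qvalue, significant = de$significant,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(0), tu_id = character(0),
               mode = character(0), log2fc = numeric(0),
               qvalue = numeric(0), significant = logical(0),
               stringsAsFactors = FALSE)
  }
  gene_rows <- gene_rows[!duplicated(gene_rows$gene_id), , drop = FALSE]
  rownames(gene_rows) <- NULL
  n_mode <- function(m) sum(gene_rows$mode == m)
  summary <- list(
    n_peaks = nrow(peaks),
    n_tus = nrow(entries),
    n_genes = nrow(gene_rows),
    n_activated = n_mode("activated"),
    n_repressed = n_mode("repressed"),
    n_not_determined = n_mode("not_determined"),
    n_conflict = n_mode("conflict"),
    n_direct_genes = n_mode("activated") + n_mode("repressed"),
    n_direct_tus = sum(entries$mode %in% c("activated", "repressed")),
    n_unassigned_peaks = length(attr(asn, "unassigned")))
  re_log(paste0("regulon: %d peaks -> %d TUs, %d genes ",
                "(%d activated / %d repressed / %d not determined)"),
         summary$n_peaks, summary$n_tus, summary$n_genes,
         summary$n_activated, summary$n_repressed,
         summary$n_not_determined)
  list(entries = entries, genes = gene_rows, summary = summary,
       assignments = asn)
}

#' Write a regulon table as TSV and its summary as JSON
#'
#' @param regulon list from [build_regulon()].
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_regulon <- function(regulon, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(regulon$entries, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(regulon$summary, json_path, auto_unbox = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
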