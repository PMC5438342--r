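#' Distribution of per-gene regulator counts across a TF panel
#'
#' Given a binary gene-by-TF membership table, tabulates how many genes
#' are regulated by exactly `k` of the TFs, with integer percentages
#' (round half up).  The union size is the number of rows (a gene appears
#' only if at least one panel TF regulates it).
#'
#' @param membership binary matrix or data.frame, genes x TFs, rownames
#'   are gene ids.
#' @return data.frame: `k`, `count`, `percent`; attribute `union_size`.
#' @export
tf_count_distribution <- function(membership) {
  m <- as.matrix(membership)
  if (!all(m %in% c(0, 1))) stop("membership entries must be 0/1")
  if (any(rowSums(m) == 0)) {
    stop("every gene in the table must be regulated by at least one TF")
  }
  k <- rowSums(m)
  total <- nrow(m)
  counts <- vapply(seq_len(ncol(m)), function(kk) sum(k == kk), 0L)
  out <- data.frame(k = seq_len(ncol(m)), count = counts,
                    percent = round_half_up(100 * counts / total))
  attr(out, "union_size") <- total
  out
}

#' Fraction of a focal regulon untouched by a TF subset
#'
#' Counts the focal genes with zero membership across the given TF
#' columns.  Focal genes absent from the table count as
#' regulated-by-zero-TFs (the table only lists genes some panel TF
#' regulates).  The percent is rounded half up; an empty focal set is
#' reported as not applicable (`NA` percent).
#'
#' @param focal_genes character vector of focal regulon gene ids.
#' @param membership binary genes x TFs table.
#' @param tf_subset TF column names to test against.
#' @return list with `count`, `total` and `percent`.
#' @export
overlap_with_tfs <- function(focal_genes, membership, tf_subset) {
  m <- as.matrix(membership)
  missing_tf <- setdiff(tf_subset, colnames(m))
  if (length(missing_tf) > 0) {
    stop("unknown TF column(s): ", paste(missing_tf, collapse = ", "))
  }
  total <- length(focal_genes)
  if (total == 0) return(list(count = 0L, total = 0L, percent = NA_real_))
  idx <- match(focal_genes, rownames(m))
  other <- m[, tf_subset, drop = FALSE]
  hits <- vapply(idx, function(i) {
    if (is.na(i)) 0 else sum(other[i, ])
  }, 0)
  count <- sum(hits == 0)
  list(count = as.integer(count), total = as.integer(total),
       percent = round_half_up(100 * count / total))
}

#' Tabulate functional categories and subcellular localization
#'
#' Counts regulon gene products per COG category letter and per
#' localization class (inner membrane, outer membrane, cytosol, not
#' determined), and reports the membrane percentage
#' (`(IM + OM) / total`, round half up).
#'
#' @param gene_ids regulon gene ids.
#' @param annotation a [genome_annotation()] carrying `cog` and
#'   `localization` per gene.
#' @return list with `cog` (named counts), `localization` (named counts
#'   over IM/OM/C/ND) and `membrane_percent`.
#' @export
tabulate_annotation <- function(gene_ids, annotation) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  g <- annotation$genes[match(gene_ids, annotation$genes$gene_id), ,
                        drop = FALSE]
  if (anyNA(g$gene_id)) stop("gene id(s) missing from annotation")
  cog <- table(g$cog)
  loc <- vapply(c("IM", "OM", "C", "ND"),
                function(l) sum(g$localization == l), 0L)
  membrane <- round_half_up(100 * (loc[["IM"]] + loc[["OM"]]) /
                              length(gene_ids))
  list(cog = cog, localization = loc, membrane_percent = membrane)
}

#' Per-gene, per-taxon-group ortholog conservation fractions
#'
#' For every gene the fraction of genomes in each taxon group that carry
#' an ortholog: presence count in the group divided by the group size.
#'
#' @param presence binary matrix, genes x genomes.
#' @param groups character vector mapping each genome (column) to its
#'   taxon group.
#' @return numeric matrix, genes x groups, fractions in `[0, 1]`; groups
#'   ordered by first appearance.
#' @export
conservation_matrix <- function(presence, groups) {
  m <- as.matrix(presence)
  if (length(groups) != ncol(m)) {
    stop("groups must map every genome column")
  }
  levels <- unique(groups)
  sizes <- vapply(levels, function(g) sum(groups == g), 0L)
  if (any(sizes == 0)) stop("empty taxon group")
  out <- vapply(levels, function(g) {
    rowMeans(m[, groups == g, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), levels))
  out
}

#' Benchmark called peaks against previously known binding sites
#'
#' A known site counts as detected when it overlaps any called peak by at
#' least one bp.  Reports the exact count and the round-half-up percent;
#' with no known sites supplied the percent is not applicable (`NA`).
#'
#' @param peaks called peak data.frame (0-based half-open).
#' @param known_sites data.frame of known intervals with `start`, `end`
#'   (0-based half-open).
#' @return list with `detected`, `total` and `percent`.
#' @export
benchmark_known_sites <- function(peaks, known_sites) {
  total <- nrow(known_sites)
  if (total == 0) {
    return(list(detected = 0L, total = 0L, percent = NA_real_))
  }
  if (nrow(peaks) == 0) {
    return(list(detected = 0L, total = as.integer(total), percent = 0))
  }
  irk <- IRanges::IRanges(known_sites$start + 1L, known_sites$end)
  irp <- IRanges::IRanges(peaks$start + 1L, peaks$end)
  hit <- IRanges::findOverlaps(irk, irp, minoverlap = 1L)
  detected <- length(unique(S4Vectors::queryHits(hit)))
  list(detected = as.integer(detected), total = as.integer(total),
       percent = round_half_up(100 * detected / total))
}

#' Maximum specific growth rate from an OD time course
#'
#' Fits a least-squares line to `ln(OD)` versus time in every sliding
#' window of `window` consecutive points and returns the largest slope
#' (per hour).  On a pure exponential the estimate equals the true rate
#' exactly.
#'
#' @param time time points in hours, strictly increasing, length >= 5.
#' @param od OD600 readings, all positive.
#' @param window points per sliding window (default 4, minimum 3).
#' @return maximum specific growth rate (1/h).
#' @export
max_growth_rate <- function(time, od, window = 4L) {
  if (length(time) != length(od)) stop("time and od lengths differ")
  if (length(time) < 5) stop("need at least 5 time points")
  if (any(diff(time) <= 0)) stop("time vector must be strictly increasing")
  if (any(od <= 0)) stop("OD values must be positive")
  if (window < 3) stop("window must span at least 3 points")
  y <- log(od)
  n <- length(time)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- time[idx]; yy <- y[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, 0)
  max(slopes)
}

#' Growth rate of a mutant relative to wild-type
#'
#' Ratio of the two maximum specific growth rates estimated under the same
#' condition.
#'
#' @param mutant,wildtype data.frames (or lists) with `time` and `od`.
#' @param window sliding-window size passed to [max_growth_rate()].
#' @return the relative rate (dimensionless).
#' @export
relative_rate <- function(mutant, wildtype, window = 4L) {
  max_growth_rate(mutant$time, mutant$od, window) /
    max_growth_rate(wildtype$time, wildtype$od, window)
}
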