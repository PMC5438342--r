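#' Integer count table for a two-condition comparison
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param condition character/factor of length `ncol(counts)` with exactly
#'   two levels, `"WT"` and `"KO"`.
#' @param gene_length per-gene length in bp.
#' @param lib_sizes per-sample library sizes; default column sums.
#' @return a `CountTable` object.
#' @export
count_table <- function(counts, condition, gene_length,
                        lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("condition length must match number of samples")
  }
  if (!setequal(unique(condition), c("WT", "KO"))) {
    stop("exactly two conditions, WT and KO, are required")
  }
  if (length(gene_length) != nrow(counts)) {
    stop("gene_length must match number of genes")
  }
  if (any(gene_length <= 0)) stop("gene lengths must be positive")
  structure(list(counts = counts, condition = condition,
                 gene_length = as.numeric(gene_length),
                 lib_sizes = as.numeric(lib_sizes)),
            class = "CountTable")
}

#' @export
print.CountTable <- function(x, ...) {
  cat(sprintf("CountTable: %d genes x %d samples (%d WT, %d KO)\n",
              nrow(x$counts), ncol(x$counts), sum(x$condition == "WT"),
              sum(x$condition == "KO")))
  invisible(x)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / ((length / 1000) * (library size / 1e6))`.  When each
#' library size equals its column sum, `sum(FPKM * length_kb)` is exactly
#' `1e6` in every sample.
#'
#' @param table a [count_table()].
#' @return numeric matrix of FPKM values, genes x samples.
#' @export
fpkm <- function(table) {
  stopifnot(inherits(table, "CountTable"))
  if (any(table$lib_sizes <= 0)) stop("library sizes must be positive")
  kb <- table$gene_length / 1000
  sweep(table$counts / kb, 2, table$lib_sizes / 1e6, "/")
}

#' Per-sample normalization factors
#'
#' `"median_ratio"` (the default) computes DESeq-style size factors: each
#' sample's median ratio to the per-gene geometric-mean reference, using
#' genes with no zero count, rescaled to geometric mean 1.  This stays
#' anchored on non-differential genes even when a large fraction of the
#' transcriptome shifts in one direction after a regulator knockout --
#' exactly the situation a regulon experiment creates.  `"libsize"` uses
#' each library size divided by the geometric mean of library sizes and is
#' adequate only when differential mass is balanced.  Median-ratio falls
#' back to library-size factors when no gene is observed in every sample.
#'
#' @param table a [count_table()].
#' @param method `"median_ratio"` or `"libsize"`.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @export
size_factors <- function(table, method = c("median_ratio", "libsize")) {
  method <- match.arg(method)
  if (method == "libsize") {
    ls <- table$lib_sizes
    return(ls / exp(mean(log(ls))))
  }
  counts <- table$counts
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) {
    ls <- table$lib_sizes
    return(ls / exp(mean(log(ls))))
  }
  logc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- exp(apply(logc - ref, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Per-gene log2 fold change, knockout over wild-type
#'
#' Counts are divided by per-sample normalization factors (see
#' [size_factors()]; median-of-ratios by default), averaged within
#' condition, and compared as
#' `log2((KO + pseudocount) / (WT + pseudocount))`.  With this orientation
#' a gene the TF activates has a negative fold change in the knockout and
#' a repressed gene a positive one.
#'
#' @param table a [count_table()].
#' @param pseudocount added to both normalized means (default 1), bounding
#'   fold changes for zero counts.
#' @param norm_method normalization passed to [size_factors()].
#' @return named numeric vector of log2 fold changes.
#' @export
estimate_log2fc <- function(table, pseudocount = 1,
                            norm_method = "median_ratio") {
  stopifnot(inherits(table, "CountTable"))
  sf <- size_factors(table, method = norm_method)
  norm <- sweep(table$counts, 2, sf, "/")
  m_ko <- rowMeans(norm[, table$condition == "KO", drop = FALSE])
  m_wt <- rowMeans(norm[, table$condition == "WT", drop = FALSE])
  stats::setNames(log2((m_ko + pseudocount) / (m_wt + pseudocount)),
                  rownames(table$counts))
}

#' Exact conditional count test per gene
#'
#' Counts are pooled within condition; conditional on the total
#' `t = KO + WT`, the pooled knockout count follows `Binomial(t, pi0)`
#' under the null of no differential expression, where `pi0` is the
#' knockout share of the total normalized library mass (the sum of
#' knockout size factors over the sum of all size factors; see
#' [size_factors()]), so that compositional shifts after a regulator
#' knockout do not bias the null.  The two-sided p-value sums
#' the probabilities of all outcomes no more likely than the observed one
#' (the minimum-likelihood rule).  Genes with `t = 0` get `p = 1`.
#'
#' @param table a [count_table()].
#' @param norm_method normalization passed to [size_factors()].
#' @return named numeric vector of p-values.
#' @export
exact_count_test <- function(table, norm_method = "median_ratio") {
  stopifnot(inherits(table, "CountTable"))
  a <- rowSums(table$counts[, table$condition == "KO", drop = FALSE])
  b <- rowSums(table$counts[, table$condition == "WT", drop = FALSE])
  sf <- size_factors(table, method = norm_method)
  pi0 <- sum(sf[table$condition == "KO"]) / sum(sf)
  p <- vapply(seq_along(a), function(i) {
    t <- a[i] + b[i]
    if (t == 0) return(1)
    d <- stats::dbinom(0:t, t, pi0)
    d_obs <- d[a[i] + 1]
    min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }, 0)
  stats::setNames(p, rownames(table$counts))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (sort ascending,
#' `q_i = min_{j >= i} p_j * n / j`, clipped at 1, returned in input
#' order), computed with [stats::p.adjust()].
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return numeric vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Flag differentially expressed genes
#'
#' A gene is significant when `|log2FC| >= lfc_min` and `q <= fdr_max`
#' (defaults 1.0 and 0.01).  Both up- and down-regulated genes qualify.
#'
#' @param results data.frame with columns `log2fc` and `qvalue` (as
#'   produced by [run_diffexpr()]).
#' @param lfc_min minimum absolute log2 fold change.
#' @param fdr_max maximum BH q-value.
#' @return the data.frame with a logical `significant` column.
#' @export
call_deg <- function(results, lfc_min = 1.0, fdr_max = 0.01) {
  results$significant <- abs(results$log2fc) >= lfc_min &
    results$qvalue <= fdr_max
  results
}

#' Run the full differential-expression stage
#'
#' Computes log2 fold changes, exact conditional test p-values, BH
#' q-values and the significance flag for every gene.  The whole stage is
#' deterministic given the count table.
#'
#' @param table a [count_table()].
#' @param lfc_min,fdr_max significance thresholds (see [call_deg()]).
#' @param pseudocount see [estimate_log2fc()].
#' @param norm_method normalization passed to [size_factors()].
#' @return data.frame: `gene_id`, `log2fc`, `pvalue`, `qvalue`,
#'   `significant`.
#' @export
run_diffexpr <- function(table, lfc_min = 1.0, fdr_max = 0.01,
                         pseudocount = 1, norm_method = "median_ratio") {
  lfc <- estimate_log2fc(table, pseudocount = pseudocount,
                         norm_method = norm_method)
  p <- exact_count_test(table, norm_method = norm_method)
  q <- bh_fdr(p)
  res <- data.frame(gene_id = rownames(table$counts), log2fc = unname(lfc),
                    pvalue = unname(p), qvalue = unname(q),
                    stringsAsFactors = FALSE)
  res <- call_deg(res, lfc_min = lfc_min, fdr_max = fdr_max)
  re_log("diffexpr: %d of %d genes significant (|lfc|>=%.2f, q<=%.3g)",
         sum(res$significant), nrow(res), lfc_min, fdr_max)
  res
}

#' Write / read a differential-expression table as TSV
#'
#' @param results data.frame from [run_diffexpr()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_de_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
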