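#' Strand-specific 5'-border count profile
#'
#' A `BorderProfile` holds the per-position counts of sequenced 5' read
#' ends for one strand of one ChIP-exo library (replicate or mock-IP) as a
#' dense vector over `[0, genome_length)`.  Lambda-exonuclease digestion
#' stops at the boundary of the protein-bound footprint, so forward-strand
#' borders pile up at the left footprint edge and reverse-strand borders at
#' the right edge; that strand-paired geometry is what the peak caller
#' exploits.
#'
#' @param counts numeric vector of non-negative counts, one per genome
#'   position.
#' @param strand `"+"` or `"-"`.
#' @param label library label, e.g. `"rep1"`, `"rep2"`, `"mock"`.
#' @param library_size total raw read count; defaults to `sum(counts)`.
#' @param normalized logical; `TRUE` once scaled to reads-per-million.
#' @return a `BorderProfile` object.
#' @export
border_profile <- function(counts, strand, label = "rep1",
                           library_size = sum(counts), normalized = FALSE) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!normalized && abs(sum(counts) - library_size) > 1e-6) {
    stop("library_size must equal sum of counts for a raw profile")
  }
  structure(list(counts = as.numeric(counts), strand = strand,
                 label = label, library_size = as.numeric(library_size),
                 normalized = normalized),
            class = "BorderProfile")
}

#' @export
print.BorderProfile <- function(x, ...) {
  cat(sprintf("BorderProfile %s(%s): %d bp, library size %s%s\n",
              x$label, x$strand, length(x$counts),
              format(x$library_size, big.mark = ","),
              if (x$normalized) " (RPM-normalized)" else ""))
  invisible(x)
}

#' Depth-normalize a border profile to reads per million
#'
#' Each positional count is multiplied by `1e6 / library_size` so that
#' replicate libraries of different sequencing depth are comparable; the
#' total mass of every normalized profile is exactly `1e6`.
#'
#' @param profile a [border_profile()].
#' @return the normalized `BorderProfile`.
#' @export
normalize_depth <- function(profile) {
  stopifnot(inherits(profile, "BorderProfile"))
  if (profile$library_size <= 0) stop("zero library size")
  if (profile$normalized) return(profile)
  profile$counts <- profile$counts * (1e6 / profile$library_size)
  profile$normalized <- TRUE
  profile
}

#' Write a border profile as bedGraph
#'
#' Zero runs are compressed; a comment header records the genome length,
#' strand, label and library size so the file round-trips losslessly
#' through [read_bedgraph()].
#'
#' @param profile a [border_profile()].
#' @param path output path.
#' @param seqname chromosome name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, seqname = "chr") {
  stopifnot(inherits(profile, "BorderProfile"))
  g <- length(profile$counts)
  header <- c(
    sprintf("track type=bedGraph name=\"%s_%s\"", profile$label,
            if (profile$strand == "+") "fwd" else "rev"),
    sprintf("# regulonexo genome_length=%d strand=%s label=%s library_size=%s normalized=%d",
            g, profile$strand, profile$label,
            format(profile$library_size, scientific = FALSE),
            as.integer(profile$normalized)))
  r <- rle(profile$counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  body <- if (any(keep)) {
    sprintf("%s\t%d\t%d\t%s", seqname, starts[keep], ends[keep],
            format(r$values[keep], scientific = FALSE, trim = TRUE,
                   digits = 15))
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a bedGraph border profile
#'
#' Intervals are 0-based half-open; overlapping intervals are rejected.
#' Metadata (genome length, strand, label, library size) is taken from the
#' header written by [write_bedgraph()] when present, otherwise from the
#' arguments.
#'
#' @param path bedGraph file.
#' @param genome_length genome length in bp (required when the file has no
#'   metadata header).
#' @param strand,label overrides for files without a metadata header.
#' @return a [border_profile()].
#' @export
read_bedgraph <- function(path, genome_length = NULL, strand = "+",
                          label = "rep1") {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  library_size <- NULL
  normalized <- FALSE
  records <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "# regulonexo")) {
      kv <- regmatches(ln, gregexpr("[a-z_]+=[^ ]+", ln))[[1]]
      meta <- stats::setNames(sub("^[a-z_]+=", "", kv),
                              sub("=.*$", "", kv))
      if ("genome_length" %in% names(meta)) {
        genome_length <- as.integer(meta[["genome_length"]])
      }
      if ("strand" %in% names(meta)) strand <- meta[["strand"]]
      if ("label" %in% names(meta)) label <- meta[["label"]]
      if ("library_size" %in% names(meta)) {
        library_size <- as.numeric(meta[["library_size"]])
      }
      if ("normalized" %in% names(meta)) {
        normalized <- meta[["normalized"]] == "1"
      }
      next
    }
    if (startsWith(ln, "#") || startsWith(ln, "track")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4) {
      stop(sprintf("parse error at line %d: expected 4 fields", i))
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || is.na(v)) {
      stop(sprintf("parse error at line %d: non-numeric fields", i))
    }
    if (v < 0) stop(sprintf("validation error at line %d: negative value", i))
    records[[length(records) + 1L]] <- c(s, e, v)
  }
  if (is.null(genome_length)) {
    stop("genome_length not given and no metadata header found")
  }
  counts <- numeric(genome_length)
  if (length(records) > 0) {
    m <- do.call(rbind, records)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2])) {
      stop("validation error: overlapping intervals in bedGraph")
    }
    if (any(m[, 2] > genome_length)) {
      stop("validation error: interval beyond genome length")
    }
    for (j in seq_len(nrow(m))) {
      counts[(m[j, 1] + 1L):m[j, 2]] <- m[j, 3]
    }
  }
  border_profile(counts, strand = strand, label = label,
                 library_size = library_size %||% sum(counts),
                 normalized = normalized)
}
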