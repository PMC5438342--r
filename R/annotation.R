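#' Genome annotation: genes grouped into transcription units
#'
#' Internal coordinates are 0-based, half-open everywhere in the package;
#' conversion to the 1-based inclusive GFF3 convention happens only at file
#' boundaries.  Every gene belongs to exactly one transcription unit (TU);
#' each TU carries one transcription start site (TSS) positioned at or
#' upstream (strand-aware) of its first gene.
#'
#' @param genes data.frame with columns `gene_id`, `tu_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), and optionally `cog`
#'   (single-letter functional category) and `localization`
#'   (`IM`/`OM`/`C`/`ND`).
#' @param tus data.frame with columns `tu_id`, `tss` (0-based position),
#'   `strand`.
#' @param genome_length genome length in bp.
#' @return a `GenomeAnnotation` object.
#' @export
genome_annotation <- function(genes, tus, genome_length) {
  stopifnot(is.data.frame(genes), is.data.frame(tus))
  need <- c("gene_id", "tu_id", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("tu_id", "tss", "strand") %in% names(tus))) {
    stop("tus must have columns tu_id, tss, strand")
  }
  if (!"cog" %in% names(genes)) genes$cog <- "S"
  if (!"localization" %in% names(genes)) genes$localization <- "ND"
  genes$length <- genes$end - genes$start
  if (any(genes$length <= 0)) stop("validation error: gene end <= start")
  if (any(genes$start < 0 | genes$end > genome_length)) {
    stop("validation error: gene interval outside genome")
  }
  if (!all(genes$tu_id %in% tus$tu_id)) {
    stop("validation error: gene references unknown TU")
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(tus$tu_id)) stop("duplicate TU ids")
  ## TSS must sit at or upstream (strand-aware) of the TU's first gene
  for (i in seq_len(nrow(tus))) {
    g <- genes[genes$tu_id == tus$tu_id[i], , drop = FALSE]
    if (nrow(g) == 0) next
    if (tus$strand[i] == "+") {
      if (tus$tss[i] > min(g$start)) {
        stop("validation error: TSS downstream of first gene (",
             tus$tu_id[i], ")")
      }
    } else {
      if (tus$tss[i] < max(g$end) - 1L) {
        stop("validation error: TSS downstream of first gene (",
             tus$tu_id[i], ")")
      }
    }
  }
  structure(list(genes = genes, tus = tus,
                 genome_length = as.integer(genome_length)),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes in %d TUs over %d bp\n",
              nrow(x$genes), nrow(x$tus), x$genome_length))
  invisible(x)
}

.parse_gff_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) x[2], ""),
                  vapply(kv, function(x) x[1], ""))
}

#' Read a genome annotation from GFF3 or BED
#'
#' The dialect is declared by the file extension: `.gff`/`.gff3` is parsed
#' as 1-based inclusive and converted to internal 0-based half-open
#' coordinates, `.bed` is already 0-based half-open.  GFF files are expected
#' to carry `gene` rows with `ID`, `tu_id` and optional `cog`/`localization`
#' attributes plus one `transcription_unit` row per TU whose strand-aware
#' 5' end is the TSS (the layout produced by [write_annotation()]).  BED
#' input (BED6 plus a seventh `tu_id` column) carries no explicit TSS; each
#' TU's TSS is taken as the strand-aware 5' end of its first gene.
#'
#' @param path annotation file.
#' @param genome_length genome length in bp; for GFF input it defaults to
#'   the `##sequence-region` header when present.
#' @return a [genome_annotation()] object.
#' @export
read_annotation <- function(path, genome_length = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    .read_annotation_gff(path, genome_length)
  } else if (ext == "bed") {
    .read_annotation_bed(path, genome_length)
  } else {
    stop("unknown annotation dialect (extension ", ext,
         "); expected .gff, .gff3 or .bed")
  }
}

.read_annotation_gff <- function(path, genome_length) {
  lines <- readLines(path)
  genes <- list(); tus <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "##sequence-region")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (is.null(genome_length) && length(f) >= 4) {
        genome_length <- as.integer(f[4])
      }
      next
    }
    if (startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop(sprintf("parse error at line %d: expected 9 tab-separated fields",
                   i))
    }
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1)) {
      stop(sprintf("parse error at line %d: non-numeric coordinates", i))
    }
    start0 <- start1 - 1L   # 1-based inclusive -> 0-based half-open
    end0 <- end1
    if (end0 <= start0) {
      stop(sprintf("validation error at line %d: end <= start", i))
    }
    at <- .parse_gff_attributes(f[9])
    if (f[3] == "gene") {
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = unname(at[["ID"]]), tu_id = unname(at[["tu_id"]]),
        start = start0, end = end0, strand = f[7],
        cog = if ("cog" %in% names(at)) unname(at[["cog"]]) else "S",
        localization = if ("localization" %in% names(at))
          unname(at[["localization"]]) else "ND",
        stringsAsFactors = FALSE)
    } else if (f[3] == "transcription_unit") {
      tss <- if (f[7] == "+") start0 else end0 - 1L
      tus[[length(tus) + 1L]] <- data.frame(
        tu_id = unname(at[["ID"]]), tss = tss, strand = f[7],
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(genome_length)) {
    stop("genome_length not given and no ##sequence-region header found")
  }
  genome_annotation(do.call(rbind, genes), do.call(rbind, tus),
                    genome_length)
}

.read_annotation_bed <- function(path, genome_length) {
  lines <- readLines(path)
  genes <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 7) {
      stop(sprintf(
        "parse error at line %d: expected >= 7 fields (BED6 + tu_id)", i))
    }
    start0 <- suppressWarnings(as.integer(f[2]))
    end0 <- suppressWarnings(as.integer(f[3]))
    if (is.na(start0) || is.na(end0)) {
      stop(sprintf("parse error at line %d: non-numeric coordinates", i))
    }
    if (end0 <= start0) {
      stop(sprintf("validation error at line %d: end <= start", i))
    }
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = f[4], tu_id = f[7], start = start0, end = end0,
      strand = f[6],
      cog = if (length(f) >= 8) f[8] else "S",
      localization = if (length(f) >= 9) f[9] else "ND",
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  if (is.null(genome_length)) genome_length <- max(genes$end)
  ## derive TSS as the strand-aware 5' end of each TU's first gene
  tus <- do.call(rbind, lapply(split(genes, genes$tu_id), function(g) {
    data.frame(tu_id = g$tu_id[1],
               tss = if (g$strand[1] == "+") min(g$start) else max(g$end) - 1L,
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(tus) <- NULL
  genome_annotation(genes, tus, genome_length)
}

#' Write a genome annotation as GFF3
#'
#' Writes one `transcription_unit` row per TU (its strand-aware 5' end is
#' the TSS) followed by `gene` rows carrying `ID`, `tu_id`, `cog` and
#' `localization` attributes.  Internal 0-based half-open coordinates are
#' converted to 1-based inclusive on output; [read_annotation()] inverts
#' the conversion exactly.
#'
#' @param annotation a [genome_annotation()] object.
#' @param path output `.gff` path.
#' @param seqname chromosome name used in column 1.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, seqname = "chr") {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqname,
                     annotation$genome_length))
  for (i in seq_len(nrow(annotation$tus))) {
    tu <- annotation$tus[i, ]
    g <- annotation$genes[annotation$genes$tu_id == tu$tu_id, ,
                          drop = FALSE]
    if (tu$strand == "+") {
      s0 <- tu$tss; e0 <- max(g$end)
    } else {
      s0 <- min(g$start); e0 <- tu$tss + 1L
    }
    lines <- c(lines, sprintf(
      "%s\tregulonexo\ttranscription_unit\t%d\t%d\t.\t%s\t.\tID=%s",
      seqname, s0 + 1L, e0, tu$strand, tu$tu_id))
  }
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    lines <- c(lines, sprintf(
      "%s\tregulonexo\tgene\t%d\t%d\t.\t%s\t.\tID=%s;tu_id=%s;cog=%s;localization=%s",
      seqname, g$start + 1L, g$end, g$strand, g$gene_id, g$tu_id, g$cog,
      g$localization))
  }
  writeLines(lines, path)
  invisible(path)
}
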