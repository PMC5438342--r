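DNA_BASES <- c("A", "C", "G", "T")

.encode_dna <- function(s) {
  v <- match(strsplit(toupper(as.character(s)), "")[[1]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains non-ACGT characters")
  v
}

.decode_dna <- function(code) paste(DNA_BASES[code], collapse = "")

## reverse complement of a 4 x w probability (or log-probability) matrix
.rc_matrix <- function(mat) {
  out <- mat[4:1, rev(seq_len(ncol(mat))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Position weight matrix constructor
#'
#' @param mat 4 x w matrix of per-position base probabilities, rows in
#'   A, C, G, T order; every column must sum to 1.
#' @param bg background base frequencies (length 4, sums to 1).
#' @return a `PWM` object.
#' @export
pwm <- function(mat, bg = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4) stop("PWM width must be >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    stop("every PWM column must sum to 1")
  }
  if (abs(sum(bg) - 1) > 1e-9) stop("background must sum to 1")
  rownames(mat) <- DNA_BASES
  structure(list(mat = mat, bg = stats::setNames(as.numeric(bg),
                                                 DNA_BASES)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM of width %d, consensus %s\n", ncol(x$mat),
              iupac_consensus(x)))
  invisible(x)
}

#' Extract peak sequences from the genome
#'
#' One uppercase sequence per peak, the peak interval extended by `flank`
#' bp on both sides and clipped at the genome ends.
#'
#' @param peaks peak data.frame (0-based half-open `start`/`end`).
#' @param genome a [Biostrings::DNAString] or character string.
#' @param flank bp added on each side (default 10).
#' @return named character vector of sequences.
#' @export
extract_peak_sequences <- function(peaks, genome, flank = 10L) {
  genome <- as.character(genome)
  g <- nchar(genome)
  starts <- pmax(0L, peaks$start - flank)
  ends <- pmin(g, peaks$end + flank)
  out <- toupper(substring(genome, starts + 1L, ends))
  names(out) <- peaks$peak_id
  out
}

## per-offset log likelihood-ratio scores of all windows of `code`
## against `lmat` (4 x w log-prob matrix, column-major) minus background
.window_scores <- function(code, lmat, lbg, w) {
  m <- length(code) - w + 1L
  if (m < 1L) return(numeric(0))
  s <- numeric(m)
  for (j in seq_len(w)) {
    b <- code[j:(j + m - 1L)]
    s <- s + lmat[(j - 1L) * 4L + b] - lbg[b]
  }
  s
}

#' Discover a binding motif by expectation-maximization
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) model: each sequence
#' contains, with prior probability `prior`, a single motif occurrence at a
#' uniformly chosen offset on either strand, and is pure background
#' otherwise.  The background is the pooled mononucleotide composition of
#' the input.  EM runs from `restarts` random initializations (columns
#' drawn from a flat Dirichlet) seeded deterministically from `seed`; the
#' restart with the highest final objective wins, ties broken by restart
#' index.  The maximized objective is the penalized log-likelihood (data
#' log-likelihood plus the Dirichlet pseudocount prior on the matrix),
#' which is non-decreasing over iterations by the usual EM argument.
#'
#' The fitted matrix is reported in a canonical orientation: if the
#' majority of called sites lie on the reverse strand, the matrix and all
#' site strands are flipped, so the forward-strand consensus is stable
#' across restarts that converge to mirror-image solutions.
#'
#' @param sequences character vector (>= 2 sequences, each >= `width`).
#' @param width motif width in bp.
#' @param restarts number of random restarts.
#' @param max_iter EM iteration cap per restart.
#' @param seed RNG seed for the restart initializations.
#' @param prior per-sequence occurrence probability (ZOOPS gamma).
#' @param pseudocount Dirichlet pseudocount per base per column.
#' @param tol relative objective-change convergence tolerance.
#' @return list with elements `pwm` (a [pwm()]), `sites` (data.frame of
#'   per-sequence best sites: `seq`, `offset` 0-based, `strand`, `prob`,
#'   `called`), `objective` (trace of the winning restart), `loglik`
#'   (final data log-likelihood), `restart` (index of the winner) and
#'   `consensus`.
#' @export
discover_motif <- function(sequences, width = 10L, restarts = 20L,
                           max_iter = 200L, seed = 1L, prior = 0.9,
                           pseudocount = 0.25, tol = 1e-8) {
  sequences <- as.character(sequences)
  if (length(sequences) < 2) stop("need at least 2 sequences")
  codes <- lapply(sequences, .encode_dna)
  lens <- lengths(codes)
  if (all(lens < width)) stop("all sequences shorter than motif width")
  if (any(lens < width)) {
    codes <- codes[lens >= width]
    re_log("discover_motif: dropped %d sequence(s) shorter than width",
           sum(lens < width))
  }
  n <- length(codes)
  w <- as.integer(width)
  comp <- lapply(codes, function(x) 5L - x)
  ## fixed background from pooled composition
  bg <- tabulate(unlist(codes), 4) + 1
  bg <- bg / sum(bg)
  lbg <- log(bg)
  const_bg <- vapply(codes, function(cd) sum(lbg[cd]), 0)

  run_em <- function(mat0) {
    mat <- mat0
    obj_trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iter)) {
      lmat <- log(mat)
      rcl <- .rc_matrix(lmat)
      cnt <- matrix(pseudocount, 4L, w)
      ll <- 0
      for (si in seq_len(n)) {
        cd <- codes[[si]]
        m <- length(cd) - w + 1L
        lf <- .window_scores(cd, lmat, lbg, w)
        lr <- .window_scores(cd, rcl, lbg, w)
        lp_site <- log(prior / (2 * m))
        lognum <- c(log(1 - prior), lp_site + lf, lp_site + lr)
        mx <- max(lognum)
        num <- exp(lognum - mx)
        tot <- sum(num)
        ll <- ll + mx + log(tot) + const_bg[si]
        z <- num / tot
        zf <- z[2:(m + 1L)]
        zr <- z[(m + 2L):(2L * m + 1L)]
        cc <- comp[[si]]
        for (j in seq_len(w)) {
          b <- cd[j:(j + m - 1L)]
          for (bb in 1:4) cnt[bb, j] <- cnt[bb, j] + sum(zf[b == bb])
          b2 <- cc[(w - j + 1L):(w - j + m)]
          for (bb in 1:4) cnt[bb, j] <- cnt[bb, j] + sum(zr[b2 == bb])
        }
      }
      ## penalized objective at the current parameters (the quantity EM
      ## is guaranteed not to decrease): data log-likelihood plus the
      ## Dirichlet pseudocount prior, both evaluated at `mat`
      obj <- ll + pseudocount * sum(log(mat))
      obj_trace <- c(obj_trace, obj)
      if (is.finite(prev) && obj - prev < tol * (abs(obj) + 1)) break
      prev <- obj
      mat <- sweep(cnt, 2, colSums(cnt), "/")
    }
    list(mat = mat, objective = obj_trace, loglik = ll)
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  ## initialize restarts from observed w-mers (the usual EM seeding
  ## strategy; far less prone to phase-shifted local optima than random
  ## matrices).  The pool is sorted so the draw is invariant under
  ## permutation of the input sequences.
  pool <- sort(unique(unlist(lapply(codes, function(cd) {
    m <- length(cd) - w + 1L
    vapply(seq_len(m), function(o) .decode_dna(cd[o:(o + w - 1L)]), "")
  }))))
  inits <- replicate(restarts, {
    kmer <- .encode_dna(pool[sample.int(length(pool), 1L)])
    m0 <- matrix(0.1, 4L, w)
    m0[cbind(kmer, seq_len(w))] <- 0.7
    m0
  }, simplify = FALSE)

  fits <- lapply(inits, run_em)
  finals <- vapply(fits, function(f) f$objective[length(f$objective)], 0)
  best_i <- which.max(finals)
  best <- fits[[best_i]]
  mat <- best$mat
  re_log("discover_motif: restart %d wins (objective %.3f)", best_i,
         finals[best_i])

  score_sites <- function(mat) {
    lmat <- log(mat)
    rcl <- .rc_matrix(lmat)
    do.call(rbind, lapply(seq_len(n), function(si) {
      cd <- codes[[si]]
      m <- length(cd) - w + 1L
      lf <- .window_scores(cd, lmat, lbg, w)
      lr <- .window_scores(cd, rcl, lbg, w)
      lp_site <- log(prior / (2 * m))
      lognum <- c(log(1 - prior), lp_site + lf, lp_site + lr)
      z <- exp(lognum - max(lognum))
      z <- z / sum(z)
      site_z <- z[-1]
      j <- which.max(site_z)
      data.frame(seq = si,
                 offset = (j - 1L) %% m,
                 strand = if (j <= m) "+" else "-",
                 prob = site_z[j], called = site_z[j] > z[1],
                 stringsAsFactors = FALSE)
    }))
  }
  sites <- score_sites(mat)
  ## canonical orientation: majority strand of called sites is forward
  called <- sites[sites$called, , drop = FALSE]
  if (nrow(called) > 0 && sum(called$strand == "-") >
        sum(called$strand == "+")) {
    mat <- .rc_matrix(mat)
    sites$strand <- ifelse(sites$strand == "+", "-", "+")
  }
  fit_pwm <- pwm(mat, bg)
  list(pwm = fit_pwm, sites = sites, objective = best$objective,
       loglik = best$loglik, restart = best_i,
       consensus = iupac_consensus(fit_pwm))
}

IUPAC_2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
IUPAC_3 <- c(ACG = "V", ACT = "H", AGT = "D", CGT = "B")

#' IUPAC base set of an ambiguity code
#'
#' @param code single IUPAC letter.
#' @return character vector of the bases it denotes.
#' @export
iupac_bases <- function(code) {
  full <- c(A = "A", C = "C", G = "G", T = "T", M = "AC", R = "AG",
            W = "AT", S = "CG", Y = "CT", K = "GT", V = "ACG", H = "ACT",
            D = "AGT", B = "CGT", N = "ACGT")
  strsplit(full[[toupper(code)]], "")[[1]]
}

#' IUPAC consensus string of a PWM
#'
#' Per column: the single top base if its probability is at least 0.6;
#' otherwise the two-base ambiguity code if the top two sum to at least
#' 0.8; otherwise the three-base code if the top three sum to at least
#' 0.95; otherwise `N`.  The thresholds are this package's stated
#' convention.
#'
#' @param x a [pwm()] or a bare 4 x w probability matrix.
#' @return consensus string of length `w`.
#' @export
iupac_consensus <- function(x) {
  mat <- if (inherits(x, "PWM")) x$mat else as.matrix(x)
  rownames(mat) <- DNA_BASES
  letters <- vapply(seq_len(ncol(mat)), function(j) {
    p <- sort(mat[, j], decreasing = TRUE)
    if (p[1] >= 0.6) return(names(p)[1])
    if (p[1] + p[2] >= 0.8) {
      key <- paste(sort(names(p)[1:2]), collapse = "")
      return(IUPAC_2[[key]])
    }
    if (p[1] + p[2] + p[3] >= 0.95) {
      key <- paste(sort(names(p)[1:3]), collapse = "")
      return(IUPAC_3[[key]])
    }
    "N"
  }, "")
  paste(letters, collapse = "")
}

#' Scan a sequence with a PWM
#'
#' Log2-odds score against the PWM background at every offset on both
#' strands; reverse-strand windows are scored with the
#' reverse-complemented matrix.
#'
#' @param sequence character or [Biostrings::DNAString].
#' @param x a [pwm()].
#' @param score_min minimum log2-odds score reported.
#' @return data.frame of hits: `offset` (0-based), `strand`, `score`.
#' @export
scan_pwm <- function(sequence, x, score_min = 0) {
  stopifnot(inherits(x, "PWM"))
  code <- .encode_dna(sequence)
  w <- ncol(x$mat)
  if (length(code) < w) stop("sequence shorter than PWM width")
  l2 <- log2(x$mat)
  l2bg <- log2(x$bg)
  sf <- .window_scores(code, l2, l2bg, w)
  sr <- .window_scores(code, .rc_matrix(l2), l2bg, w)
  hits <- data.frame(
    offset = c(seq_along(sf), seq_along(sr)) - 1L,
    strand = rep(c("+", "-"), c(length(sf), length(sr))),
    score = c(sf, sr), stringsAsFactors = FALSE)
  hits <- hits[hits$score >= score_min, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(-hits$score), , drop = FALSE]
}

#' Write a PWM as a MEME-minimal-format text block
#'
#' @param x a [pwm()].
#' @param path output path.
#' @param name motif name in the file.
#' @return `path`, invisibly.
#' @export
write_meme_pwm <- function(x, path, name = "MOTIF_1") {
  stopifnot(inherits(x, "PWM"))
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.4f", DNA_BASES, x$bg), collapse = " "),
             "",
             sprintf("MOTIF %s", name),
             sprintf(
               "letter-probability matrix: alength= 4 w= %d nsites= 0 E= 0",
               ncol(x$mat)),
             apply(x$mat, 2, function(col) {
               paste(sprintf("%.6f", col), collapse = " ")
             }))
  writeLines(lines, path)
  invisible(path)
}
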