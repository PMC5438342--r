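## Planted motif model: consensus KWWGTTACAT.  Two-base columns split
## 0.485/0.485 with 0.015 on each minor base; strong columns put 0.97 on
## the consensus base.
.planted_pwm <- function() {
  col2 <- function(b1, b2) {
    p <- rep(0.015, 4); names(p) <- DNA_BASES
    p[c(b1, b2)] <- 0.485
    p
  }
  col1 <- function(b) {
    p <- rep(0.01, 4); names(p) <- DNA_BASES
    p[b] <- 0.97
    p
  }
  mat <- cbind(col2("G", "T"), col2("A", "T"), col2("A", "T"),
               col1("G"), col1("T"), col1("T"), col1("A"), col1("C"),
               col1("A"), col1("T"))
  pwm(mat)
}

.preset_params <- function(preset) {
  if (preset == "paper_scale") {
    list(
      genome_length = 500000L, n_tus = 350L, n_genes = 600L,
      ## regulon structure: 24 TUs / 37 genes; direct 16 TUs / 26 genes
      act_sizes = c(5L, 2L, 2L, 1L, 1L, 1L, 1L, 1L),    # 14 genes
      rep_sizes = c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L),    # 12 genes
      nd_sizes = c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L),     # 11 genes
      double_site_tu = 1L,      # first activated TU carries two sites
      n_known = 8L, known_without_signal = TRUE,
      n_indirect_de = 386L,     # 412 DE genes total minus 26 direct
      depth = 2000000L, noise = 0.05, mock_artifacts = 2L,
      mean_count = 400, dispersion = 0.01,
      plant_localization = TRUE)
  } else if (preset == "small") {
    list(
      genome_length = 30000L, n_tus = 18L, n_genes = 25L,
      act_sizes = c(2L), rep_sizes = c(1L), nd_sizes = c(1L),
      double_site_tu = 0L,
      n_known = 2L, known_without_signal = FALSE,
      n_indirect_de = 4L,
      depth = 120000L, noise = 0.05, mock_artifacts = 1L,
      mean_count = 400, dispersion = 0.01,
      plant_localization = FALSE)
  } else {
    stop("unknown preset: ", preset)
  }
}

## interleaved regulon TU spec: mode and gene count per regulon TU,
## ordered along the genome
.regulon_spec <- function(pp) {
  specs <- rbind(
    data.frame(mode = "activated", size = pp$act_sizes,
               rank = seq_along(pp$act_sizes)),
    data.frame(mode = "repressed", size = pp$rep_sizes,
               rank = seq_along(pp$rep_sizes)),
    data.frame(mode = "not_determined", size = pp$nd_sizes,
               rank = seq_along(pp$nd_sizes)))
  ## interleave modes so regulon TUs of each mode spread over the genome
  specs <- specs[order(specs$rank), c("mode", "size")]
  rownames(specs) <- NULL
  specs
}

## lay out TUs and genes along the genome; regulon TUs sit at evenly
## spaced slots, are plus-stranded, are preceded by a plus-stranded TU and
## get an enlarged upstream gap so a planted site window can only reach
## its own TSS
.layout_genome <- function(pp) {
  reg <- .regulon_spec(pp)
  n_reg <- nrow(reg)
  slots <- round(seq(6, pp$n_tus - 4, length.out = n_reg))
  sizes <- rep(1L, pp$n_tus)
  sizes[slots] <- reg$size
  n_extra <- pp$n_genes - sum(sizes)
  if (n_extra < 0) stop("validation error: more regulon genes than genes")
  free <- setdiff(seq_len(pp$n_tus), c(slots, slots - 1L))
  extra_tus <- sample(free, n_extra, replace = FALSE)
  sizes[extra_tus] <- sizes[extra_tus] + 1L
  strands <- sample(c("+", "-"), pp$n_tus, replace = TRUE)
  strands[c(slots, slots - 1L)] <- "+"

  genes <- vector("list", pp$n_tus)
  tus <- vector("list", pp$n_tus)
  gaps <- list()
  pos <- 0L
  gi <- 0L
  for (t in seq_len(pp$n_tus)) {
    is_reg <- t %in% slots
    gap <- if (is_reg) 480L else sample(150:300, 1)
    gaps[[t]] <- data.frame(mid = pos + gap %/% 2L, width = gap,
                            near_regulon = is_reg || (t - 1L) %in% slots ||
                              (t + 1L) %in% slots)
    pos <- pos + gap
    n <- sizes[t]
    lens <- sample(450:750, n, replace = TRUE)
    tu_id <- sprintf("tu%03d", t)
    offs <- c(0L, cumsum(lens[-n] + 20L))   # gene offsets within block
    if (strands[t] == "+") {
      tss <- pos
      starts <- pos + 60L + offs
      block_end <- starts[n] + lens[n]
    } else {
      starts <- pos + offs
      tss <- starts[n] + lens[n] + 59L
      block_end <- tss + 1L
    }
    coords <- data.frame(start = starts, end = starts + lens)
    ids <- sprintf("g%04d", gi + seq_len(n))
    gi <- gi + n
    genes[[t]] <- data.frame(gene_id = ids, tu_id = tu_id,
                             start = coords$start, end = coords$end,
                             strand = strands[t], stringsAsFactors = FALSE)
    tus[[t]] <- data.frame(tu_id = tu_id, tss = tss, strand = strands[t],
                           stringsAsFactors = FALSE)
    pos <- block_end
  }
  if (pos >= pp$genome_length) {
    stop("validation error: layout exceeds genome length")
  }
  genes <- do.call(rbind, genes)
  tus <- do.call(rbind, tus)
  list(genes = genes, tus = tus, gaps = do.call(rbind, gaps),
       slots = slots, reg = reg,
       reg_tu_ids = sprintf("tu%03d", slots))
}

## COG letters and localization classes for the annotation; the regulon
## genes of the paper_scale preset are planted to span exactly 13 COG
## categories and an 18 IM / 7 OM / 9 C / 3 ND localization split
.decorate_genes <- function(genes, regulon_gene_ids, plant) {
  cats13 <- c("C", "E", "G", "K", "M", "N", "O", "P", "T", "U", "F",
              "H", "J")
  genes$cog <- sample(c(cats13, "S", "L", "I"), nrow(genes),
                      replace = TRUE)
  genes$localization <- sample(c("IM", "OM", "C", "ND"), nrow(genes),
                               replace = TRUE,
                               prob = c(0.2, 0.1, 0.5, 0.2))
  if (plant) {
    idx <- match(regulon_gene_ids, genes$gene_id)
    n <- length(idx)
    genes$cog[idx] <- sample(c(cats13, sample(cats13, n - 13,
                                              replace = TRUE)))
    genes$localization[idx] <- sample(c(rep("IM", 18), rep("OM", 7),
                                        rep("C", 9), rep("ND", 3)))
  }
  genes
}

## pick well-separated intergenic midpoints for artifact / known-no-signal
## sites, away from regulon neighborhoods and from each other
.pick_gap_positions <- function(gaps, n, avoid, min_dist = 2000L) {
  cand <- gaps$mid[!gaps$near_regulon & gaps$width >= 120L]
  cand <- sample(cand)
  out <- integer(0)
  for (p in cand) {
    if (length(out) == n) break
    if (all(abs(c(avoid, out) - p) >= min_dist)) out <- c(out, p)
  }
  if (length(out) < n) stop("could not place background sites")
  out
}

#' Simulate strand-specific ChIP-exo border profiles
#'
#' For every site with signal, forward-strand 5' borders pile up around
#' the left footprint edge and reverse-strand borders around the right
#' edge, each with a truncated-geometric offset (weight `0.5^|offset|`,
#' `|offset| <= jitter`); the remaining reads are uniform background.
#' Replicates are drawn independently.  The mock-IP track carries the
#' artifact sites (shared with the ChIP tracks) plus background at
#' `mock_background` of its reads.  Each strand of each library receives
#' exactly half the configured depth, so profile sums are exact.
#'
#' @param sites data.frame with `fp_start`, `fp_end` (0-based half-open
#'   footprints), `has_signal`, and `kind` (`"signal"`, `"artifact"` or
#'   `"known_nosignal"`).
#' @param genome_length genome length in bp.
#' @param depth total reads per library (split evenly between strands).
#' @param noise fraction of ChIP reads that are uniform background.
#' @param jitter maximum border offset in bp.
#' @param mock_background fraction of mock reads that are background (the
#'   rest pile at artifact sites; with no artifacts the mock is pure
#'   background).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return named list of six [border_profile()]s: `rep1_fwd`, `rep1_rev`,
#'   `rep2_fwd`, `rep2_rev`, `mock_fwd`, `mock_rev`.
#' @export
simulate_chipexo <- function(sites, genome_length, depth = 2000000L,
                             noise = 0.05, jitter = 2L,
                             mock_background = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth <= 0) stop("depth must be positive")
  g <- as.integer(genome_length)
  chip <- sites[sites$has_signal & sites$kind %in% c("signal", "artifact"),
                , drop = FALSE]
  mock <- sites[sites$kind == "artifact" & sites$has_signal, ,
                drop = FALSE]
  wts <- 0.5^abs(-jitter:jitter)
  sim_strand <- function(edges, n_reads, bg_rate) {
    pos <- integer(0)
    is_bg <- stats::runif(n_reads) < bg_rate | length(edges) == 0
    n_bg <- sum(is_bg)
    n_sig <- n_reads - n_bg
    if (n_bg > 0) pos <- sample.int(g, n_bg, replace = TRUE) - 1L
    if (n_sig > 0) {
      site <- sample.int(length(edges), n_sig, replace = TRUE)
      off <- sample(-jitter:jitter, n_sig, replace = TRUE, prob = wts)
      pos <- c(pos, pmin(g - 1L, pmax(0L, edges[site] + off)))
    }
    tabulate(pos + 1L, g)
  }
  n_fwd <- as.integer(depth %/% 2L)
  n_rev <- as.integer(depth) - n_fwd
  build <- function(label, site_set, bg_rate) {
    list(
      fwd = border_profile(sim_strand(site_set$fp_start, n_fwd, bg_rate),
                           "+", label),
      rev = border_profile(sim_strand(site_set$fp_end - 1L, n_rev,
                                      bg_rate), "-", label))
  }
  r1 <- build("rep1", chip, noise)
  r2 <- build("rep2", chip, noise)
  mk <- build("mock", mock, if (nrow(mock) > 0) mock_background else 1)
  list(rep1_fwd = r1$fwd, rep1_rev = r1$rev, rep2_fwd = r2$fwd,
       rep2_rev = r2$rev, mock_fwd = mk$fwd, mock_rev = mk$rev)
}

#' Simulate knockout-versus-wild-type RNA-seq counts
#'
#' Per gene and sample, counts are negative-binomial around a base mean
#' proportional to gene length, scaled by a per-sample library factor.
#' The knockout mean is the wild-type mean times `2^effect_lfc`, where
#' `effect_lfc` is the planted log2(KO/WT) effect: negative for genes the
#' TF activates (deleting the activator lowers its targets), positive for
#' repressed genes, zero for unchanged genes.  `dispersion = 0` gives
#' Poisson counts.
#'
#' @param genes data.frame with `gene_id`, `length` and `effect_lfc`.
#' @param mean_count base mean count for a 600 bp gene.
#' @param dispersion negative-binomial dispersion (>= 0).
#' @param n_rep samples per condition.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return a [count_table()] with samples `WT_1..`, `KO_1..`.
#' @export
simulate_rnaseq_counts <- function(genes, mean_count = 400,
                                   dispersion = 0.01, n_rep = 2L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dispersion < 0) stop("dispersion must be >= 0")
  n <- nrow(genes)
  base <- stats::runif(n, 0.6, 1.4) * mean_count * genes$length / 600
  sf <- stats::runif(2L * n_rep, 0.9, 1.1)
  mu_wt <- outer(base, sf[seq_len(n_rep)])
  mu_ko <- outer(base * 2^genes$effect_lfc,
                 sf[n_rep + seq_len(n_rep)])
  mu <- cbind(mu_wt, mu_ko)
  counts <- if (dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = n)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = n)
  }
  dimnames(counts) <- list(genes$gene_id,
                           c(paste0("WT_", seq_len(n_rep)),
                             paste0("KO_", seq_len(n_rep))))
  count_table(counts,
              condition = rep(c("WT", "KO"), each = n_rep),
              gene_length = genes$length)
}

## motif instances for the signal sites, drawn so the per-column base
## composition of the planted set matches the model frequencies exactly
## (quota sampling with largest-remainder rounding, order permuted)
.plant_instances <- function(n_sites, mat) {
  w <- ncol(mat)
  inst <- matrix(0L, n_sites, w)
  for (j in seq_len(w)) {
    quota <- floor(n_sites * mat[, j])
    rem <- n_sites * mat[, j] - quota
    short <- n_sites - sum(quota)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      quota[add] <- quota[add] + 1
    }
    inst[, j] <- sample(rep.int(1:4, quota))
  }
  inst
}

## regulon-gene effect table: per-TU mode, per-gene signed log2(KO/WT)
.plant_effects <- function(layout, genes, pp, tf_gene) {
  effect <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  mode <- stats::setNames(rep("unchanged", nrow(genes)), genes$gene_id)
  for (i in seq_along(layout$slots)) {
    tu <- layout$reg_tu_ids[i]
    ids <- genes$gene_id[genes$tu_id == tu]
    m <- layout$reg$mode[i]
    mode[ids] <- m
    if (m == "activated") effect[ids] <- -stats::runif(length(ids), 2, 4)
    if (m == "repressed") effect[ids] <- stats::runif(length(ids), 2, 4)
  }
  regulon_ids <- genes$gene_id[genes$tu_id %in% layout$reg_tu_ids]
  pool <- setdiff(genes$gene_id, c(regulon_ids, tf_gene))
  n_other <- pp$n_indirect_de - 1L
  indirect <- c(tf_gene, sample(pool, n_other))
  effect[tf_gene] <- -6
  others <- indirect[-1]
  effect[others] <- sample(c(-1, 1), length(others), replace = TRUE) *
    stats::runif(length(others), 2, 4)
  mode[indirect] <- "indirect"
  list(effect = effect, mode = mode, indirect = indirect,
       regulon_ids = regulon_ids)
}

.make_membership <- function(regulon_gene_ids, pool_ids) {
  tfs <- c("OmpR", "OxyR", "SoxR", "SoxS", "Fur", "GadE", "GadW", "GadX")
  n_focal <- length(regulon_gene_ids)
  other_ids <- sample(pool_ids, 243L - n_focal)
  genes <- c(regulon_gene_ids, other_ids)
  m <- matrix(0L, length(genes), length(tfs),
              dimnames = list(genes, tfs))
  m[regulon_gene_ids, "OmpR"] <- 1L
  ## three focal genes shared with the stress panel (dtpA-, znuA-,
  ## micF-like): one + GadX, one + OxyR, one + SoxS and GadE
  shared <- sample(regulon_gene_ids, 3)
  m[shared[1], "GadX"] <- 1L
  m[shared[2], "OxyR"] <- 1L
  m[shared[3], c("SoxS", "GadE")] <- 1L
  ## remaining genes: 172 single-TF, 31 two-TF, 3 three-TF rows so the
  ## panel totals are 206 / 33 / 4 across 243 genes
  others7 <- setdiff(tfs, "OmpR")
  kinds <- c(rep(1L, 172), rep(2L, 31), rep(3L, 3))
  for (i in seq_along(other_ids)) {
    m[other_ids[i], sample(others7, kinds[i])] <- 1L
  }
  m
}

.extend_membership <- function(m, regulon_gene_ids) {
  extra <- sprintf("TF%02d", 9:38)
  ext <- matrix(0L, nrow(m), length(extra),
                dimnames = list(rownames(m), extra))
  stress_shared <- regulon_gene_ids[
    rowSums(m[regulon_gene_ids, setdiff(colnames(m), "OmpR")]) > 0]
  free_focal <- setdiff(regulon_gene_ids, stress_shared)
  ## 16 more focal genes gain regulators outside the stress panel, so 18
  ## of 37 keep no known regulator besides the focal TF; two of them are
  ## heavily co-regulated (flhDC- and csgDEFG-like, 7 and 9 extra TFs)
  chosen <- sample(free_focal, 16)
  ext[chosen[1], sample(extra, 7)] <- 1L
  ext[chosen[2], sample(extra, 9)] <- 1L
  for (g in chosen[-(1:2)]) ext[g, sample(extra, sample(1:3, 1))] <- 1L
  non_focal <- setdiff(rownames(m), regulon_gene_ids)
  touched <- sample(non_focal, round(0.3 * length(non_focal)))
  for (g in touched) ext[g, sample(extra, sample(1:2, 1))] <- 1L
  cbind(m, ext)
}

.make_ortholog <- function(regulon_gene_ids, tf_gene, low_gene) {
  sizes <- c(Escherichia = 13L, Shigella = 3L, Salmonella = 2L,
             Yersinia = 7L, gamma = 134L, beta = 40L, alpha = 58L)
  groups <- rep(names(sizes), sizes)
  genomes <- sprintf("gnm%03d", seq_len(sum(sizes)))
  genes <- c(tf_gene, regulon_gene_ids)
  m <- matrix(0L, length(genes), length(genomes),
              dimnames = list(genes, genomes))
  ## the focal TF is retained in 97% of genomes of every group
  for (grp in names(sizes)) {
    cols <- which(groups == grp)
    keep <- sample(cols, max(1L, round(0.97 * length(cols))))
    m[tf_gene, keep] <- 1L
  }
  decay <- c(Escherichia = 1, Shigella = 0.9, Salmonella = 0.85,
             Yersinia = 0.6, gamma = 0.4, beta = 0.25, alpha = 0.15)
  for (g in regulon_gene_ids) {
    base <- if (g == low_gene) 0.08 else stats::runif(1, 0.3, 0.9)
    p <- pmin(1, base * decay[groups])
    m[g, ] <- stats::rbinom(ncol(m), 1L, p)
  }
  list(presence = m, groups = groups, group_sizes = sizes)
}

.make_growth <- function() {
  strains <- list(
    wild_type = c(normal = 1.00, osmotic = 1.00),
    yccT_oe = c(normal = 0.97, osmotic = 0.60),
    nuoN_oe = c(normal = 0.70, osmotic = 0.95),
    narU_ko = c(normal = 1.00, osmotic = 0.70),
    ompF_ko = c(normal = 0.98, osmotic = 0.79),
    narU_oe = c(normal = 1.00, osmotic = 1.36),
    ompX_ko = c(normal = 1.00, osmotic = 1.00))
  base_r <- c(normal = 0.65, osmotic = 0.45)
  k_cap <- c(normal = 1.4, osmotic = 1.1)
  tt <- seq(0, 10, by = 0.5)
  rows <- list()
  for (s in names(strains)) {
    for (cond in c("normal", "osmotic")) {
      r <- base_r[[cond]] * strains[[s]][[cond]]
      k <- k_cap[[cond]]
      od0 <- 0.02
      od <- k * od0 * exp(r * tt) / (k + od0 * (exp(r * tt) - 1))
      od <- od * exp(stats::rnorm(length(tt), 0, 0.01))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, condition = cond, time = tt, od = od,
        stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, rows),
       true_relative = strains)
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Builds a genome with motif instances planted at binding-site
#' footprints, a gene/TU annotation, duplicate ChIP-exo border profiles
#' plus a mock-IP track, knockout/wild-type RNA-seq counts, a
#' stress-TF-panel membership table (plus an extended table covering a
#' wider regulator list), an ortholog presence/absence matrix over seven
#' taxon groups, and growth curves -- all mutually consistent with a
#' `ScenarioTruth` record of what was planted.
#'
#' The `paper_scale` preset plants 25 detectable binding sites targeting
#' 24 TUs containing 37 genes (one TU carries two sites), a
#' 14 activated / 12 repressed / 11 unchanged gene split, 8
#' previously-known sites of which exactly one lacks ChIP signal, 412
#' differentially expressed genes genome-wide (26 direct plus 386
#' TF-independent), and taxon groups of 13/3/2/7/134/40/58 genomes.  The
#' `small` preset plants 3 sites in 3 TUs for fast deterministic unit
#' tests.
#'
#' @param preset `"paper_scale"` or `"small"`.
#' @param seed integer seed; the full dataset is a deterministic function
#'   of `(preset, seed)`.
#' @return a `SyntheticDataset` list: `genome` (character), `annotation`,
#'   `profiles`, `counts`, `membership`, `membership_extended`,
#'   `ortholog`, `growth`, and `truth`.
#' @export
generate_scenario <- function(preset = c("paper_scale", "small"),
                              seed = 42L) {
  preset <- match.arg(preset)
  pp <- .preset_params(preset)
  set.seed(seed)
  layout <- .layout_genome(pp)
  regulon_ids <- layout$genes$gene_id[
    layout$genes$tu_id %in% layout$reg_tu_ids]
  genes <- .decorate_genes(layout$genes, regulon_ids,
                           pp$plant_localization)
  ann <- genome_annotation(genes, layout$tus, pp$genome_length)

  ## binding sites: one per regulon TU (two for the designated TU)
  half_fp <- 15L
  site_rows <- list()
  for (i in seq_along(layout$slots)) {
    tu <- layout$tus[layout$tus$tu_id == layout$reg_tu_ids[i], ]
    dists <- if (i == pp$double_site_tu) c(80L, 280L)
             else sample(80:330, 1)
    for (d in dists) {
      center <- tu$tss - d
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        center = center, fp_start = center - half_fp,
        fp_end = center + half_fp, tu_id = tu$tu_id,
        mode = layout$reg$mode[i], kind = "signal", has_signal = TRUE,
        known = FALSE, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  n_known_signal <- pp$n_known - as.integer(pp$known_without_signal)
  sites$known[sample(nrow(sites), n_known_signal)] <- TRUE

  n_bg_sites <- pp$mock_artifacts + as.integer(pp$known_without_signal)
  bg_pos <- .pick_gap_positions(layout$gaps, n_bg_sites, sites$center)
  extra <- list()
  if (pp$known_without_signal) {
    c0 <- bg_pos[1]
    extra[[1]] <- data.frame(center = c0, fp_start = c0 - half_fp,
                             fp_end = c0 + half_fp, tu_id = NA,
                             mode = NA, kind = "known_nosignal",
                             has_signal = FALSE, known = TRUE,
                             stringsAsFactors = FALSE)
    bg_pos <- bg_pos[-1]
  }
  for (p in bg_pos) {
    extra[[length(extra) + 1L]] <- data.frame(
      center = p, fp_start = p - half_fp, fp_end = p + half_fp,
      tu_id = NA, mode = NA, kind = "artifact", has_signal = TRUE,
      known = FALSE, stringsAsFactors = FALSE)
  }
  sites <- rbind(sites, do.call(rbind, extra))
  sites$site_id <- sprintf("site_%02d", seq_len(nrow(sites)))

  ## genome sequence with motif instances planted at signal-site centers
  genome <- sample(DNA_BASES, pp$genome_length, replace = TRUE)
  planted <- .planted_pwm()
  sig_idx <- which(sites$kind == "signal")
  inst <- .plant_instances(length(sig_idx), planted$mat)
  w <- ncol(planted$mat)
  for (r in seq_along(sig_idx)) {
    s0 <- sites$center[sig_idx[r]] - w %/% 2L
    genome[(s0 + 1L):(s0 + w)] <- DNA_BASES[inst[r, ]]
  }
  genome <- paste(genome, collapse = "")

  ## expression effects, TF-gene analogue on a single-gene non-regulon TU
  single_tus <- names(which(table(genes$tu_id) == 1))
  tf_candidates <- setdiff(single_tus, layout$reg_tu_ids)
  tf_gene <- genes$gene_id[genes$tu_id == sample(tf_candidates, 1)]
  eff <- .plant_effects(layout, genes, pp, tf_gene)

  profiles <- simulate_chipexo(sites, pp$genome_length, depth = pp$depth,
                               noise = pp$noise)
  gene_tab <- data.frame(gene_id = genes$gene_id,
                         length = genes$end - genes$start,
                         effect_lfc = unname(eff$effect[genes$gene_id]),
                         stringsAsFactors = FALSE)
  counts <- simulate_rnaseq_counts(gene_tab, mean_count = pp$mean_count,
                                   dispersion = pp$dispersion)

  membership <- membership_ext <- ortholog <- NULL
  if (preset == "paper_scale") {
    pool <- setdiff(genes$gene_id, c(regulon_ids, tf_gene))
    membership <- .make_membership(regulon_ids, pool)
    membership_ext <- .extend_membership(membership, regulon_ids)
    low_gene <- genes$gene_id[genes$tu_id == layout$reg_tu_ids[1]][1]
    ortholog <- .make_ortholog(regulon_ids, tf_gene, low_gene)
  }
  growth <- .make_growth()

  known <- sites[sites$known, , drop = FALSE]
  truth <- list(
    sites = sites,
    genes = data.frame(gene_id = genes$gene_id,
                       mode = unname(eff$mode[genes$gene_id]),
                       effect_lfc = unname(eff$effect[genes$gene_id]),
                       stringsAsFactors = FALSE),
    regulon_gene_ids = regulon_ids,
    regulon_tu_ids = layout$reg_tu_ids,
    indirect_de = setdiff(eff$indirect, regulon_ids),
    de_genes = names(which(eff$effect != 0)),
    tf_gene = tf_gene,
    pwm = planted,
    known_sites = data.frame(site_id = known$site_id,
                             start = known$fp_start, end = known$fp_end,
                             has_signal = known$has_signal,
                             stringsAsFactors = FALSE),
    growth_relative = growth$true_relative,
    preset = preset, seed = seed, params = pp)
  structure(list(genome = genome, annotation = ann, profiles = profiles,
                 counts = counts, membership = membership,
                 membership_extended = membership_ext,
                 ortholog = ortholog, growth = growth$curves,
                 truth = truth),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(
    "SyntheticDataset (%s, seed %d): %d bp genome, %d genes, %d planted sites\n",
    x$truth$preset, x$truth$seed, nchar(x$genome),
    nrow(x$annotation$genes), sum(x$truth$sites$kind == "signal")))
  invisible(x)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' FASTA genome, GFF3 annotation, six bedGraph border profiles, counts and
#' sample-sheet TSVs, membership/ortholog/growth TSVs and the planted
#' truth tables.
#'
#' @param dataset a [generate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(dataset$genome)
  names(fa) <- "chr"
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fasta"))
  write_annotation(dataset$annotation, file.path(dir, "annotation.gff"))
  for (nm in names(dataset$profiles)) {
    write_bedgraph(dataset$profiles[[nm]],
                   file.path(dir, paste0(nm, ".bedgraph")))
  }
  ct <- dataset$counts
  counts_df <- data.frame(gene_id = rownames(ct$counts),
                          length = ct$gene_length, ct$counts,
                          check.names = FALSE)
  utils::write.table(counts_df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(ct$counts), condition = ct$condition),
    file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(dataset$membership)) {
    utils::write.table(
      data.frame(gene_id = rownames(dataset$membership),
                 dataset$membership, check.names = FALSE),
      file.path(dir, "membership.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = rownames(dataset$ortholog$presence),
                 dataset$ortholog$presence, check.names = FALSE),
      file.path(dir, "ortholog.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(genome = colnames(dataset$ortholog$presence),
                 group = dataset$ortholog$groups),
      file.path(dir, "ortholog_groups.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  utils::write.table(dataset$growth, file.path(dir, "growth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a counts TSV plus sample sheet back into a count table
#'
#' @param counts_path TSV with `gene_id`, `length` and one column per
#'   sample.
#' @param samples_path TSV with `sample` and `condition` columns.
#' @return a [count_table()].
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ss <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, ss$sample, drop = FALSE])
  rownames(counts) <- df$gene_id
  count_table(counts, condition = ss$condition, gene_length = df$length)
}
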