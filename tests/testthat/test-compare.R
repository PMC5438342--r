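test_that("round_half_up matches the printed-figure convention", {
  expect_equal(round_half_up(87.5), 88)    # 7/8
  expect_equal(round_half_up(91.89), 92)   # 34/37
  expect_equal(round_half_up(67.57), 68)   # 25/37
  expect_equal(round_half_up(84.77), 85)   # 206/243
  expect_equal(round_half_up(48.65), 49)   # 18/37
  expect_equal(round_half_up(12.5), 13)    # where round() would give 12
})

panel_membership <- function() {
  ## 243 genes: 206 single-TF, 33 double-TF, 3 triple, 1 quadruple
  tfs <- c("OmpR", "OxyR", "SoxR", "SoxS", "Fur", "GadE", "GadW", "GadX")
  m <- matrix(0L, 243, 8, dimnames = list(sprintf("x%03d", 1:243), tfs))
  set.seed(3)
  for (i in 1:206) m[i, sample(8, 1)] <- 1L
  for (i in 207:239) m[i, sample(8, 2)] <- 1L
  for (i in 240:242) m[i, sample(8, 3)] <- 1L
  m[243, sample(8, 4)] <- 1L
  m
}

test_that("TF-count distribution reports counts and rounded percents", {
  dist <- tf_count_distribution(panel_membership())
  expect_equal(attr(dist, "union_size"), 243)
  expect_equal(dist$count[1:4], c(206, 33, 3, 1))
  expect_equal(dist$percent[1], 85)        # 206/243
  expect_equal(dist$percent[2], 14)        # 33/243 = 13.58 rounds up
  expect_equal(sum(dist$count), 243)
  expect_lte(abs(sum(dist$percent) - 100), 1)
  ## all genes under every TF collapses to a single bin at k = 8
  all_m <- matrix(1L, 5, 8, dimnames = list(letters[1:5], colnames(
    panel_membership())))
  d2 <- tf_count_distribution(all_m)
  expect_equal(d2$count[8], 5)
  expect_equal(d2$percent[8], 100)
  expect_true(all(d2$count[1:7] == 0))
})

test_that("regulon overlap with other TFs reproduces the printed ratios", {
  tfs <- c("OmpR", "OxyR", "SoxS", "GadE", "GadX")
  m <- matrix(0L, 40, 5, dimnames = list(sprintf("f%02d", 1:40), tfs))
  m[1:37, "OmpR"] <- 1L
  m[1, "GadX"] <- 1L; m[2, "OxyR"] <- 1L; m[3, c("SoxS", "GadE")] <- 1L
  focal <- sprintf("f%02d", 1:37)
  got <- overlap_with_tfs(focal, m, setdiff(tfs, "OmpR"))
  expect_equal(got$count, 34)
  expect_equal(got$percent, 92)            # 34/37
  ## genes absent from the table count as zero-membership
  got2 <- overlap_with_tfs(c(focal, "absent1"), m, setdiff(tfs, "OmpR"))
  expect_equal(got2$count, 35)
  ## 18 of 37 -> 49
  m2 <- m
  m2[4:19, "OxyR"] <- 1L                   # 16 more focal genes touched
  got3 <- overlap_with_tfs(focal, m2, setdiff(tfs, "OmpR"))
  expect_equal(got3$count, 18)
  expect_equal(got3$percent, 49)
  empty <- overlap_with_tfs(character(0), m, "OxyR")
  expect_true(is.na(empty$percent))
  expect_error(overlap_with_tfs(focal, m, "NoSuchTF"), "unknown TF")
})

test_that("localization tabulation reproduces the membrane percentage", {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:37), tu_id = "tu1",
    start = seq(0, by = 100, length.out = 37),
    end = seq(90, by = 100, length.out = 37), strand = "+",
    cog = "C",
    localization = c(rep("IM", 18), rep("OM", 7), rep("C", 9),
                     rep("ND", 3)))
  tus <- data.frame(tu_id = "tu1", tss = 0, strand = "+")
  ann <- genome_annotation(genes, tus, 5000)
  tab <- tabulate_annotation(genes$gene_id, ann)
  expect_equal(unname(tab$localization), c(18L, 7L, 9L, 3L))
  expect_equal(tab$membrane_percent, 68)   # 25/37
  expect_equal(sum(tab$localization), 37)
  ## all-cytosolic gives zero membrane percent
  genes$localization <- "C"
  ann2 <- genome_annotation(genes, tus, 5000)
  expect_equal(tabulate_annotation(genes$gene_id, ann2)$membrane_percent,
               0)
})

test_that("the planted regulon spans 13 COG categories and 68% membrane", {
  ds <- paper_dataset()
  tab <- tabulate_annotation(ds$truth$regulon_gene_ids, ds$annotation)
  expect_equal(length(tab$cog), 13)
  expect_equal(tab$membrane_percent, 68)
})

test_that("conservation fractions are exact and permutation-invariant", {
  presence <- rbind(tf = c(1, 1, 1, 1, 0, 1),
                    g1 = c(1, 1, 0, 1, 0, 0),
                    g2 = rep(0, 6))
  groups <- c("A", "A", "A", "B", "B", "B")
  cm <- conservation_matrix(presence, groups)
  expect_equal(cm["tf", ], c(A = 1, B = 2 / 3))
  expect_equal(cm["g1", "A"], 2 / 3)
  expect_equal(unname(cm["g2", ]), c(0, 0))
  ## permuting genomes within a group leaves the fractions unchanged
  perm <- c(3, 1, 2, 6, 5, 4)
  cm2 <- conservation_matrix(presence[, perm], groups[perm])
  expect_equal(cm2, cm)
  expect_error(conservation_matrix(presence, groups[1:5]), "map every")
})

test_that("the focal TF is more conserved than its regulon on average", {
  ds <- paper_dataset()
  cm <- conservation_matrix(ds$ortholog$presence, ds$ortholog$groups)
  tf_row <- cm[ds$truth$tf_gene, ]
  reg_rows <- cm[ds$truth$regulon_gene_ids, ]
  expect_gt(mean(tf_row), mean(reg_rows))
})

test_that("known-site benchmark counts >= 1 bp overlaps, rounded half-up", {
  peaks <- data.frame(start = c(100, 500, 900), end = c(130, 530, 930))
  known <- data.frame(start = c(95, 529, 2000, 905, 910, 1500, 1600,
                                1700),
                      end = c(115, 560, 2030, 935, 940, 1530, 1630, 1730))
  got <- benchmark_known_sites(peaks, known)
  expect_equal(got$detected, 4)
  expect_equal(got$percent, 50)
  ## every site overlapped gives 100
  got_all <- benchmark_known_sites(peaks, known[c(1, 2, 4, 5), ])
  expect_equal(got_all$detected, 4)
  expect_equal(got_all$percent, 100)
  expect_true(is.na(benchmark_known_sites(peaks,
                                          known[0, ])$percent))
  none <- benchmark_known_sites(peaks[0, ], known)
  expect_equal(none$percent, 0)
})

test_that("benchmark percent rises as the S/N threshold is relaxed", {
  ds <- small_dataset()
  prof <- lapply(ds$profiles, normalize_depth)
  merged <- reproducible_peaks(
    call_candidate_peaks(prof$rep1_fwd, prof$rep1_rev),
    call_candidate_peaks(prof$rep2_fwd, prof$rep2_rev))
  known <- ds$truth$known_sites
  last <- -1
  for (sn_min in rev(c(0.5, 1, 200, 1e4))) {
    pk <- filter_peaks(merged, NULL, sn_min = sn_min)
    pct <- benchmark_known_sites(pk, known)$percent
    expect_gte(pct, last)
    last <- pct
  }
})

test_that("growth-rate estimation is exact on pure exponentials", {
  t <- seq(0, 5, by = 0.5)
  od <- 0.02 * exp(0.6 * t)
  expect_equal(max_growth_rate(t, od), 0.6, tolerance = 1e-10)
  expect_equal(relative_rate(list(time = t, od = od),
                             list(time = t, od = od)), 1)
  expect_error(max_growth_rate(rev(t), od), "increasing")
  expect_error(max_growth_rate(t[1:4], od[1:4]), "at least 5")
  expect_error(max_growth_rate(t, od - 1), "positive")
})

test_that("logistic growth is recovered within 5% of the true rate", {
  r <- 0.8; k <- 1.5; od0 <- 0.01
  t <- seq(0, 12, by = 0.1)
  od <- k * od0 * exp(r * t) / (k + od0 * (exp(r * t) - 1))
  est <- max_growth_rate(t, od)
  expect_lt(abs(est - r) / r, 0.05)
})

test_that("planted growth phenotypes are recovered from the curves", {
  ds <- small_dataset()
  g <- ds$growth
  curve <- function(strain, cond) {
    rows <- g[g$strain == strain & g$condition == cond, ]
    list(time = rows$time, od = rows$od)
  }
  wt_osm <- curve("wild_type", "osmotic")
  expect_equal(relative_rate(curve("yccT_oe", "osmotic"), wt_osm), 0.60,
               tolerance = 0.1)
  expect_equal(relative_rate(curve("narU_oe", "osmotic"), wt_osm), 1.36,
               tolerance = 0.1)
  expect_equal(relative_rate(curve("narU_ko", "osmotic"), wt_osm), 0.70,
               tolerance = 0.1)
})
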