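test_that("generation is fully deterministic given the seed", {
  a <- generate_scenario("small", seed = 11)
  b <- generate_scenario("small", seed = 11)
  expect_identical(a$genome, b$genome)
  expect_identical(a$profiles$rep1_fwd$counts, b$profiles$rep1_fwd$counts)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$sites, b$truth$sites)
  c <- generate_scenario("small", seed = 12)
  expect_false(identical(a$genome, c$genome))
})

test_that("small preset plants 3 sites in 3 TUs", {
  ds <- small_dataset()
  sig <- ds$truth$sites[ds$truth$sites$kind == "signal", ]
  expect_equal(nrow(sig), 3)
  expect_equal(length(unique(sig$tu_id)), 3)
  expect_setequal(unique(ds$truth$genes$mode),
                  c("activated", "repressed", "not_determined",
                    "unchanged", "indirect"))
})

test_that("paper_scale preset plants the full study structure", {
  ds <- paper_dataset()
  truth <- ds$truth
  sig <- truth$sites[truth$sites$kind == "signal", ]
  expect_equal(nrow(sig), 25)
  expect_equal(length(unique(sig$tu_id)), 24)
  expect_equal(length(truth$regulon_gene_ids), 37)
  known <- truth$sites[truth$sites$known, ]
  expect_equal(nrow(known), 8)
  expect_equal(sum(known$has_signal), 7)
  modes <- truth$genes[truth$genes$gene_id %in% truth$regulon_gene_ids, ]
  expect_equal(sum(modes$mode == "activated"), 14)
  expect_equal(sum(modes$mode == "repressed"), 12)
  expect_equal(sum(modes$mode == "not_determined"), 11)
  expect_equal(length(truth$de_genes), 412)
  expect_true(all(abs(truth$genes$effect_lfc[
    truth$genes$gene_id %in% truth$de_genes]) >= 2))
  expect_equal(unname(ds$ortholog$group_sizes),
               c(13L, 3L, 2L, 7L, 134L, 40L, 58L))
  ## focal TF retained in at least 95% of all genomes
  expect_gte(mean(ds$ortholog$presence[truth$tf_gene, ]), 0.95)
  expect_lt(mean(ds$ortholog$presence[truth$regulon_gene_ids, ]),
            mean(ds$ortholog$presence[truth$tf_gene, ]))
})

test_that("every planted site footprint lies inside its target TSS window", {
  ds <- paper_dataset()
  sig <- ds$truth$sites[ds$truth$sites$kind == "signal", ]
  tus <- ds$annotation$tus
  d <- distance_to_tss(sig$center, tus$tss[match(sig$tu_id, tus$tu_id)],
                       tus$strand[match(sig$tu_id, tus$tu_id)])
  expect_true(all(d >= -500 & d <= 200))
})

test_that("profile read depth matches the configured library split exactly", {
  ds <- small_dataset()
  depth <- ds$truth$params$depth
  expect_equal(sum(ds$profiles$rep1_fwd$counts) +
                 sum(ds$profiles$rep1_rev$counts), depth)
  expect_equal(sum(ds$profiles$rep2_fwd$counts) +
                 sum(ds$profiles$rep2_rev$counts), depth)
  expect_equal(ds$profiles$mock_fwd$library_size,
               sum(ds$profiles$mock_fwd$counts))
})

test_that("zero-noise borders stay within the jitter of footprint edges", {
  sites <- data.frame(center = 500L, fp_start = 485L, fp_end = 515L,
                      kind = "signal", has_signal = TRUE)
  prof <- simulate_chipexo(sites, 2000L, depth = 1000L, noise = 0,
                           seed = 5)
  fwd_pos <- which(prof$rep1_fwd$counts > 0) - 1L
  rev_pos <- which(prof$rep1_rev$counts > 0) - 1L
  expect_true(all(abs(fwd_pos - 485L) <= 2))
  expect_true(all(abs(rev_pos - 514L) <= 2))
})

test_that("border midpoints recover planted centers within 2 bp at zero noise", {
  devs <- unlist(lapply(1:20, function(s) {
    set.seed(1000 + s)
    centers <- sort(sample(seq(800, 19000, by = 600), 3))
    sites <- data.frame(center = centers, fp_start = centers - 15L,
                        fp_end = centers + 15L, kind = "signal",
                        has_signal = TRUE)
    prof <- simulate_chipexo(sites, 20000L, depth = 20000L, noise = 0)
    fwd <- normalize_depth(prof$rep1_fwd)
    rev <- normalize_depth(prof$rep1_rev)
    peaks <- call_candidate_peaks(fwd, rev)
    vapply(centers, function(cc) min(abs(peaks$center - cc)), 0)
  }))
  expect_lte(mean(devs), 2)
})

test_that("negative-binomial count means follow the planted effects", {
  genes <- data.frame(gene_id = c("act", "flat"), length = c(600, 600),
                      effect_lfc = c(-2, 0))
  ## dispersion 0 gives Poisson draws; with a large mean the empirical
  ## ratio pins the planted 2^-2 scaling
  set.seed(9)
  tabs <- replicate(200, {
    ct <- simulate_rnaseq_counts(genes, mean_count = 400, dispersion = 0)
    rowMeans(ct$counts[, 3:4]) / rowMeans(ct$counts[, 1:2])
  })
  expect_equal(mean(tabs[1, ]), 0.25, tolerance = 0.05)
  expect_equal(mean(tabs[2, ]), 1, tolerance = 0.05)
})

test_that("membership table reproduces the planted panel structure", {
  ds <- paper_dataset()
  m <- ds$membership
  expect_equal(nrow(m), 243)
  expect_equal(ncol(m), 8)
  k <- rowSums(m)
  expect_equal(sum(k == 1), 206)
  expect_equal(sum(k == 2), 33)
  expect_equal(sum(k >= 3), 4)
  ## 34 of the 37 focal genes untouched by the other 7 stress TFs
  focal <- ds$truth$regulon_gene_ids
  expect_equal(sum(rowSums(m[focal, colnames(m) != "OmpR"]) == 0), 34)
  ## 18 of 37 untouched across the extended regulator list
  ext <- ds$membership_extended
  expect_equal(sum(rowSums(ext[focal, colnames(ext) != "OmpR"]) == 0), 18)
})

test_that("dataset writes to disk in standard text formats", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fasta", "annotation.gff", "rep1_fwd.bedgraph",
    "mock_rev.bedgraph", "counts.tsv", "samples.tsv", "growth.tsv",
    "truth_sites.tsv")))))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  expect_equal(as.character(fa[[1]]), ds$genome)
})
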