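make_profile <- function(counts, strand = "+", label = "rep1",
                         normalized = FALSE) {
  border_profile(counts, strand = strand, label = label,
                 normalized = normalized)
}

test_that("depth normalization scales to reads per million", {
  p <- make_profile(c(rep(0, 9), 4), label = "rep1")
  p$library_size <- 2e6; p$counts[10] <- 4  # value 4 at 2M reads -> 2 RPM
  p2 <- normalize_depth(p)
  expect_equal(p2$counts[10], 2)
  q <- border_profile(rep(1, 10), "+", library_size = 1e6,
                      normalized = TRUE)
  q$normalized <- FALSE
  expect_equal(normalize_depth(q)$counts, rep(1, 10))
  bad <- make_profile(rep(0, 5))
  expect_error(normalize_depth(bad), "zero library size")
})

test_that("normalized replicate profiles carry total mass 1e6", {
  ds <- small_dataset()
  for (nm in c("rep1_fwd", "rep2_rev")) {
    expect_equal(sum(normalize_depth(ds$profiles[[nm]])$counts), 1e6)
  }
})

test_that("an all-uniform profile yields zero candidates", {
  v <- rep(2, 5000)
  fwd <- border_profile(v, "+", normalized = TRUE, library_size = 1e4)
  rev <- border_profile(v, "-", normalized = TRUE, library_size = 1e4)
  expect_equal(nrow(call_candidate_peaks(fwd, rev)), 0)
})

test_that("a single planted site is called at its footprint edges", {
  sites <- data.frame(center = 2500L, fp_start = 2485L, fp_end = 2515L,
                      kind = "signal", has_signal = TRUE)
  prof <- simulate_chipexo(sites, 5000L, depth = 4000L, noise = 0,
                           seed = 3)
  peaks <- call_candidate_peaks(normalize_depth(prof$rep1_fwd),
                                normalize_depth(prof$rep1_rev))
  expect_equal(nrow(peaks), 1)
  expect_lte(abs(peaks$fwd_border - 2485L), 2)
  expect_lte(abs(peaks$rev_border - 2514L), 2)
})

test_that("distant sites pair their own borders without cross-pairing", {
  centers <- c(2000L, 7000L)
  sites <- data.frame(center = centers, fp_start = centers - 15L,
                      fp_end = centers + 15L, kind = "signal",
                      has_signal = TRUE)
  prof <- simulate_chipexo(sites, 10000L, depth = 8000L, noise = 0,
                           seed = 4)
  fwd <- normalize_depth(prof$rep1_fwd)
  rev <- normalize_depth(prof$rep1_rev)
  peaks <- call_candidate_peaks(fwd, rev)
  expect_equal(nrow(peaks), 2)
  ## brute-force pairing oracle: each forward border must pair with the
  ## nearest downstream reverse border within the span cap
  fb <- peaks$fwd_border; rb <- peaks$rev_border
  for (i in seq_along(fb)) {
    cand <- rb[rb >= fb[i] & rb - fb[i] <= 100]
    expect_equal(peaks$rev_border[i], min(cand))
  }
  expect_true(all(peaks$end - peaks$start < 40))
})

test_that("signal-to-noise is the ratio of peak to genome mean density", {
  v <- rep(10, 1000); v[101:110] <- 50
  fwd <- border_profile(v / 2, "+", normalized = TRUE, library_size = 1)
  rev <- border_profile(v / 2, "-", normalized = TRUE, library_size = 1)
  peak <- data.frame(start = 100L, end = 110L)
  gmean <- mean(v)
  expect_equal(signal_to_noise(peak, fwd, rev), 50 / gmean)
  flat <- border_profile(rep(5, 1000), "+", normalized = TRUE,
                         library_size = 1)
  expect_equal(signal_to_noise(peak, flat, flat), 1)
  zero <- border_profile(rep(0, 1000), "+", normalized = TRUE,
                         library_size = 1)
  expect_error(signal_to_noise(peak, zero, zero), "zero genome-wide")
})

random_peakset <- function(n, g = 10000) {
  start <- sort(sample.int(g - 120, n))
  end <- start + sample(10:100, n, replace = TRUE)
  data.frame(peak_id = sprintf("p%03d", seq_len(n)), start = start,
             end = end, center = floor((start + end) / 2),
             fwd_border = start, rev_border = end - 1L,
             sn = runif(n, 0.5, 10), support = "rep",
             stringsAsFactors = FALSE)
}

test_that("reproducible_peaks matches a quadratic all-pairs oracle", {
  set.seed(77)
  for (rep in 1:100) {
    p1 <- random_peakset(sample(3:12, 1))
    p2 <- random_peakset(sample(3:12, 1))
    got <- reproducible_peaks(p1, p2)
    ## oracle: all pairs with >= 1 bp interval overlap, merged by union
    exp_rows <- list()
    for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
      if (p1$start[i] < p2$end[j] && p2$start[j] < p1$end[i]) {
        exp_rows[[length(exp_rows) + 1L]] <- data.frame(
          start = min(p1$start[i], p2$start[j]),
          end = max(p1$end[i], p2$end[j]),
          sn = (p1$sn[i] + p2$sn[j]) / 2)
      }
    }
    if (length(exp_rows) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      want <- unique(do.call(rbind, exp_rows))
      want <- want[order(want$start, want$end), , drop = FALSE]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$sn, want$sn)
    }
  }
})

test_that("reproducible_peaks is symmetric and idempotent on identical input", {
  set.seed(8)
  p1 <- random_peakset(8)
  p2 <- random_peakset(8)
  ab <- reproducible_peaks(p1, p2)
  ba <- reproducible_peaks(p2, p1)
  expect_equal(ab[c("start", "end", "sn")], ba[c("start", "end", "sn")])
  self <- reproducible_peaks(p1, p1)
  expect_true(all(p1$start %in% self$start))
  only1 <- p1[1, , drop = FALSE]
  far <- p1[3, , drop = FALSE]; far$start <- far$start + 5000
  far$end <- far$end + 5000
  expect_equal(nrow(reproducible_peaks(only1, far)), 0)
})

test_that("filtering removes low S/N peaks and mock-overlapping peaks", {
  p <- random_peakset(4)
  p$sn <- c(0.9, 5, 3, 2)
  mock <- p[3, , drop = FALSE]   # same interval as peak 3
  kept <- filter_peaks(p, mock, sn_min = 1)
  expect_setequal(kept$peak_id, p$peak_id[c(2, 4)])
  expect_equal(nrow(filter_peaks(p, NULL, sn_min = 1)), 3)
})

test_that("a mock artifact overlapping a planted site removes exactly that site", {
  centers <- c(3000L, 9000L)
  sites <- data.frame(
    center = c(centers, centers[1]),
    fp_start = c(centers - 15L, centers[1] - 15L),
    fp_end = c(centers + 15L, centers[1] + 15L),
    kind = c("signal", "signal", "artifact"),
    has_signal = TRUE)
  prof <- simulate_chipexo(sites, 12000L, depth = 24000L, noise = 0.05,
                           seed = 21)
  prof <- lapply(prof, normalize_depth)
  c1 <- call_candidate_peaks(prof$rep1_fwd, prof$rep1_rev)
  c2 <- call_candidate_peaks(prof$rep2_fwd, prof$rep2_rev)
  mock <- filter_peaks(call_candidate_peaks(prof$mock_fwd, prof$mock_rev),
                       NULL, sn_min = 1)
  final <- filter_peaks(reproducible_peaks(c1, c2), mock, sn_min = 1)
  expect_equal(nrow(final), 1)
  expect_lte(abs(final$center - 9000L), 3)
})

test_that("peak count is monotone non-increasing in sn_min and k", {
  ds <- small_dataset()
  prof <- lapply(ds$profiles, normalize_depth)
  merged <- reproducible_peaks(
    call_candidate_peaks(prof$rep1_fwd, prof$rep1_rev),
    call_candidate_peaks(prof$rep2_fwd, prof$rep2_rev))
  n_last <- Inf
  for (sn_min in c(0.5, 1, 50, 500)) {
    n <- nrow(filter_peaks(merged, NULL, sn_min = sn_min))
    expect_lte(n, n_last)
    n_last <- n
  }
  n_last <- Inf
  for (k in c(2, 3, 10)) {
    n <- nrow(call_candidate_peaks(prof$rep1_fwd, prof$rep1_rev, k = k))
    expect_lte(n, n_last)
    n_last <- n
  }
})
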