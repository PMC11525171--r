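mk_members <- function(r2, dprime, lead_first = TRUE) {
  n <- length(r2)
  data.frame(locus_id = "L1", variant_id = sprintf("v%02d", 1:n),
             chrom = "chr1", pos = 1:n * 100,
             is_lead = c(lead_first, rep(FALSE, n - 1)),
             r2_to_lead = r2, dprime_to_lead = dprime)
}

test_that("AVS membership requires both LD thresholds; the lead is free", {
  m <- mk_members(r2 = c(NA, 0.85, 0.85, 0.79), dprime = c(NA, 0.9, 0.7, 0.9))
  avs <- build_avs(m)
  expect_setequal(avs$variant_id, c("v01", "v02"))
  lone <- build_avs(mk_members(r2 = NA_real_, dprime = NA_real_))
  expect_equal(nrow(lone), 1L)
})

background_pool <- function(n, in_peak_frac, peak_start = 1e6) {
  # points 1..n placed inside or outside a single peak deterministically
  inside <- seq_len(n) <= round(n * in_peak_frac)
  data.frame(id = sprintf("b%04d", seq_len(n)), chrom = "chr1",
             pos = ifelse(inside, peak_start + seq_len(n),
                          2e6 + seq_len(n)))
}

test_that("the observed AVS tally counts loci with any peak overlap", {
  avs <- data.frame(locus_id = rep(c("A", "B", "C"), each = 2),
                    variant_id = sprintf("v%d", 1:6), chrom = "chr1",
                    pos = c(150, 950, 2000, 3000, 180, 990))
  peaks <- interval_track("chr1", c(100, 900), c(200, 1000))
  bg <- background_pool(200, 0.3, peak_start = 100)
  res <- avs_enrichment(avs, peaks, bg, n_perm = 50, seed = 5)
  expect_equal(res$observed_tally, 2L)  # loci A and C overlap, B does not
  resv <- avs_enrichment(avs, peaks, bg, n_perm = 50, seed = 5,
                         tally = "variants")
  expect_equal(resv$observed_tally, 4L)
})

test_that("the empirical p is the >= proportion; smoothing adds one", {
  avs <- data.frame(locus_id = "A", variant_id = "v1", chrom = "chr1",
                    pos = 150)
  peaks <- interval_track("chr1", 0, 3e6)  # saturating peak
  bg <- background_pool(100, 0.5)
  res <- avs_enrichment(avs, peaks, bg, n_perm = 200, seed = 1)
  expect_equal(res$observed_tally, 1L)
  expect_true(all(res$null_tallies == 1L))
  expect_equal(res$p_value, 1)
  # no peak at all: observed 0, every null >= 0, p = 1 either way
  none <- interval_track(character(), numeric(), numeric())
  res0 <- avs_enrichment(avs, none, bg, n_perm = 100, seed = 1)
  expect_equal(res0$p_value, 1)
  sm <- avs_enrichment(avs, peaks, bg, n_perm = 199, seed = 1, smooth = TRUE)
  expect_equal(sm$p_value, (199 + 1) / (199 + 1))
})

test_that("fixed seeds give bit-identical null tallies", {
  avs <- data.frame(locus_id = rep(c("A", "B"), each = 3),
                    variant_id = sprintf("v%d", 1:6), chrom = "chr1",
                    pos = c(150, 950, 2000, 3000, 180, 990))
  peaks <- interval_track("chr1", c(100, 900), c(200, 1000))
  bg <- background_pool(500, 0.4, peak_start = 100)
  r1 <- avs_enrichment(avs, peaks, bg, n_perm = 300, seed = 99)
  r2 <- avs_enrichment(avs, peaks, bg, n_perm = 300, seed = 99)
  expect_identical(r1$null_tallies, r2$null_tallies)
  expect_true(all(r1$null_tallies <= 2L))  # bounded by the number of AVS
})

test_that("a background pool smaller than the AVS is an error", {
  avs <- data.frame(locus_id = "A", variant_id = sprintf("v%d", 1:5),
                    chrom = "chr1", pos = 1:5 * 10)
  peaks <- interval_track("chr1", 0, 100)
  expect_error(avs_enrichment(avs, peaks, background_pool(3, 0.5),
                              n_perm = 10, seed = 1), "smaller")
})

test_that("TF count enrichment sums bound sites over regions", {
  # five regions with bound-site counts 3, 0, 2, 1, 1 -> observed 7
  regions <- interval_track("chr1", c(0, 1000, 2000, 3000, 4000),
                            c(500, 1500, 2500, 3500, 4500))
  site_start <- c(10, 20, 30, 2100, 2200, 3100, 4100, 9000)
  sites <- data.frame(chrom = "chr1", start = site_start,
                      end = site_start + 5,
                      tf = "CTCF", bound = c(rep(1L, 7), 1L))
  pool <- data.frame(id = sprintf("n%d", 1:50), chrom = "chr1",
                     pos = 1e6 + 1:50 * 100)
  res <- tf_count_enrichment(regions, sites, pool, n_perm = 100, seed = 3)
  expect_equal(res$observed_tally, 7L)
  # the pool's windows never reach a site: all null counts 0, p = 0
  expect_true(all(res$null_tallies == 0L))
  expect_equal(res$p_value, 0)
  # observed 0 gives p = 1 under the >= rule
  far <- interval_track("chr1", 5e5, 5e5 + 100)
  res0 <- tf_count_enrichment(far, sites, pool, n_perm = 50, seed = 3)
  expect_equal(res0$observed_tally, 0L)
  expect_equal(res0$p_value, 1)
  # unbound sites are never counted
  sites0 <- transform(sites, bound = 0L)
  expect_equal(tf_count_enrichment(regions, sites0, pool, n_perm = 10,
                                   seed = 1)$observed_tally, 0L)
})

test_that("a small null pool falls back to with-replacement sampling", {
  regions <- interval_track("chr1", c(0, 1000), c(500, 1500))
  sites <- data.frame(chrom = "chr1", start = 10, end = 20, tf = "SP1",
                      bound = 1L)
  pool <- data.frame(id = "n1", chrom = "chr1", pos = 250)
  expect_warning(res <- tf_count_enrichment(regions, sites, pool,
                                            n_perm = 20, seed = 1),
                 "with replacement")
  # every null window is centred on pos 250 with width 500 -> contains the
  # site every time
  expect_true(all(res$null_tallies >= 1L))
})
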