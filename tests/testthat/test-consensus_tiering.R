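test_that("majority consensus retains a level only on a strict majority", {
  expect_equal(majority_consensus(c(2, 2, 2, 2, 0, 0))$value, 2L)
  expect_equal(majority_consensus(c(2, 2, 2, 0, 0, 0))$value, 0L)
  # level-wise: 2 strong + 3 weak of 6 means 5/6 score >= 1
  m <- majority_consensus(c(2, 2, 1, 1, 1, 0))
  expect_equal(m$value, 1L)
  expect_equal(m$n_supporting, 5L)
  expect_equal(m$n_cell_lines, 6L)
  # NA cell lines leave the denominator
  expect_equal(majority_consensus(c(2, 2, NA, NA))$value, 2L)
  expect_warning(z <- majority_consensus(c(NA, NA)), "no cell line")
  expect_equal(z$value, 0L)
})

test_that("majority consensus is permutation-invariant and 0-monotone", {
  set.seed(41)
  for (rep in 1:50) {
    v <- sample(0:2, sample(1:8, 1), replace = TRUE)
    base <- majority_consensus(v)$value
    expect_equal(majority_consensus(v[sample.int(length(v))])$value, base)
    expect_lte(majority_consensus(c(v, 0L))$value, base)
  }
})

test_that("binomial consensus reproduces the exact tail probabilities", {
  # n = 6, k = 3: tail P = 0.01585 -> score 1
  expect_equal(binomial_consensus(3, 6), 1L)
  # n = 6, k = 4: tail P = 0.00127 -> score 2
  expect_equal(binomial_consensus(4, 6), 2L)
  # n = 6, k = 1: tail P = 0.4686 -> score 0
  expect_equal(binomial_consensus(1, 6), 0L)
  # k = 0 and n = 0 short-circuit
  expect_equal(binomial_consensus(0, 6), 0L)
  expect_equal(binomial_consensus(0, 0), 0L)
})

test_that("percentile flags are inclusive and handle degenerate scores", {
  tabs <- list(
    A = data.frame(item_id = c("v1", "v2", "v3", sprintf("f%d", 1:17)),
                   score = c(0.95, 0.5, 0.99, seq(0.01, 0.8,
                                                  length.out = 17))),
    B = data.frame(item_id = c("v1", "v2"), score = c(1, 1)))
  fl <- percentile_hit_flags(tabs)
  a <- fl[fl$cell_line == "A", ]
  expect_true(all(a$flag[a$item_id %in% c("v1", "v3")]))
  expect_false(a$flag[a$item_id == "v2"])
  # all scores identical: q90 equals the common value, every flag true
  b <- fl[fl$cell_line == "B", ]
  expect_true(all(b$flag))
  # v3 absent from B: excluded from that cell line entirely
  expect_false("v3" %in% b$item_id)
  # boundary: best score exactly at the q90 value flags true
  x <- data.frame(item_id = sprintf("i%02d", 1:10), score = 1:10)
  q <- quantile(1:10, 0.9, names = FALSE)
  fx <- percentile_hit_flags(list(C = x))
  expect_identical(fx$flag, x$score >= q)
})

test_that("score summation adds all terms and rejects duplicates", {
  ts <- data.frame(variant_id = rep("v1", 5),
                   term = c("MPRA_a", "MPRA_b", "MPRA_c", "FINEMAP", "ATAC"),
                   value = c(2L, 1L, 0L, 2L, 2L))
  expect_equal(sum_scores(ts)$total_score, 7L)
  dup <- rbind(ts, ts[4, ])
  expect_error(sum_scores(dup), "duplicated")
  zero <- data.frame(variant_id = "v2", term = "ATAC", value = 0L)
  expect_equal(sum_scores(zero)$total_score, 0L)
})

test_that("tier assignment splits 20/30/50 and promotes boundary ties", {
  ten <- data.frame(variant_id = sprintf("v%02d", 1:10),
                    total_score = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  tt <- assign_tiers(ten)
  expect_equal(as.vector(table(tt$tier)), c(2L, 3L, 5L))
  expect_equal(tt$tier[tt$total_score >= 9], c(1L, 1L))

  all_same <- data.frame(variant_id = sprintf("v%02d", 1:10),
                         total_score = rep(4L, 10))
  expect_true(all(assign_tiers(all_same)$tier == 1L))

  single <- data.frame(variant_id = "v1", total_score = 0L)
  expect_equal(assign_tiers(single)$tier, 1L)

  # a tie spanning the Tier1/Tier2 boundary promotes the whole block
  tie <- data.frame(variant_id = sprintf("v%02d", 1:10),
                    total_score = c(9, 9, 9, 9, 5, 5, 3, 2, 1, 0))
  expect_equal(sum(assign_tiers(tie)$tier == 1L), 4L)
})

test_that("tiers are monotone in score and percentile is a top fraction", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(1:40, 1)
    tt <- assign_tiers(data.frame(variant_id = sprintf("v%02d", 1:n),
                                  total_score = sample(0:8, n,
                                                       replace = TRUE)))
    expect_true(all(diff(tt$tier) >= 0))        # sorted by rank
    expect_true(all(diff(tt$rank_percentile) >= 0))
    expect_gte(sum(tt$tier == 1L), ceiling(0.2 * n))
    expect_lte(sum(tt$tier == 3L), floor(0.5 * n))
    # equal scores always share a tier
    expect_true(all(tapply(tt$tier, tt$total_score,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("planted causal variants are tiered above background", {
  sim <- simulate_dataset(sim_config(n_loci = 5, variants_per_locus = 16,
                                     frac_causal = 1 / 16,
                                     signal_strength = 1,
                                     background_rate = 0.05, seed = 99))
  res <- run_pipeline(sim$dir, file.path(sim$dir, "out"))
  t1 <- res$tiers$variant_id[res$tiers$tier == 1L]
  causal <- sim$truth$variant_id
  frac_causal_t1 <- mean(causal %in% t1)
  bg <- setdiff(res$tiers$variant_id, causal)
  expect_gt(frac_causal_t1, mean(bg %in% t1))
})
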