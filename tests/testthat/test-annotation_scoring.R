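cfg <- scoring_config()

test_that("MPRA scores follow the FDR thresholds with inclusive bounds", {
  expect_equal(score_mpra(c(5e-4, 1e-3, 0.05, 0.2, NA), cfg),
               c(2L, 2L, 1L, 0L, 0L))
})

test_that("fine-mapping scores combine PIP and credible-set membership", {
  expect_equal(score_finemap(0.7, TRUE, cfg), 2L)
  expect_equal(score_finemap(0.7, FALSE, cfg), 2L)  # PIP rule dominates
  expect_equal(score_finemap(0.1, TRUE, cfg), 1L)
  expect_equal(score_finemap(0.0004, FALSE, cfg), 0L)
  lit <- scoring_config(finemap_literal_pip = TRUE)
  expect_equal(score_finemap(0.0004, FALSE, lit), 1L)
})

test_that("chromatin-state scores come from the configured map", {
  seg <- interval_track("chr1", c(0, 100, 200), c(100, 200, 300),
                        label = c("EnhA", "EnhWk", "Quies"))
  mycfg <- scoring_config(chromhmm_state_map = c(EnhA = 2L, EnhWk = 1L,
                                                 Quies = 0L))
  v <- mk_variants(c(50, 150, 250))
  expect_equal(score_chromhmm(v, seg, mycfg), c(2L, 1L, 0L))
  # uncovered position: 0 with a warning; unmapped label: 0
  v2 <- mk_variants(c(350, 50))
  expect_warning(got <- score_chromhmm(v2, seg, scoring_config()),
                 "not covered")
  expect_equal(got, c(0L, 0L))
})

test_that("peak overlap scores 2/0 and respects half-open ends", {
  peaks <- interval_track("chr1", 100, 200)
  # 201 is the first position past the half-open end
  v <- mk_variants(c(150, 50, 201))
  expect_equal(score_peak_overlap(v, peaks), c(2L, 0L, 0L))
})

test_that("SMR term scores 2 per tissue with a passing link", {
  normal <- data.frame(variant_id = "v1", gene_id = "g1")
  tumor <- data.frame(variant_id = "v2", gene_id = "g1")
  expect_equal(score_smr(c("v1", "v2", "v3"), normal), c(2L, 0L, 0L))
  expect_equal(score_smr(c("v1", "v2", "v3"), tumor), c(0L, 2L, 0L))
})

test_that("disruption scores follow the window-fraction rule", {
  # 1000 scored positions; the top decile is 901:1000 by construction
  trk <- data.frame(chrom = "chr1", pos = 1:1000, score = 1:1000 / 1000)
  # variant at 950: window 850..1000, 100 of 151 positions in the top
  # decile (f90 = 0.66)
  expect_equal(score_akita(mk_variants(950), trk, cfg), 2L)
  # variant at 790: window 690..890; none in top decile, 90 of 201 in the
  # top quintile (f80 = 0.45)
  expect_equal(score_akita(mk_variants(790), trk, cfg), 1L)
  # all window scores below q80
  expect_equal(score_akita(mk_variants(300), trk, cfg), 0L)
  # empty window warns and scores 0
  expect_warning(z <- score_akita(mk_variants(5000), trk, cfg), "no scored")
  expect_equal(z, 0L)
})

test_that("disruption scores match a position-scan oracle (property)", {
  set.seed(31)
  for (rep in 1:5) {
    trk <- data.frame(chrom = "chr1", pos = sort(sample(1:10000, 600)),
                      score = rexp(600))
    q90 <- quantile(trk$score, 0.9, names = FALSE)
    q80 <- quantile(trk$score, 0.8, names = FALSE)
    pos <- sample(150:9850, 40)
    got <- score_akita(mk_variants(pos), trk, cfg)
    want <- vapply(pos, function(p) {
      w <- trk$score[abs(trk$pos - p) <= 100]
      if (!length(w)) return(0L)
      if (mean(w >= q90) > 0.25) 2L else if (mean(w >= q80) > 0.25) 1L else 0L
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("chromatin contacts score TSS > body and filter by significance", {
  genes <- gene_models(c("gA", "gB"), "chr1", c(10000, 20000),
                       c(15000, 25000), c(10001, 22000), c("+", "+"))
  v <- mk_variants(500, id = "v1")
  tss_ia <- data.frame(chrom_a = "chr1", start_a = 400, end_a = 600,
                       chrom_b = "chr1", start_b = 9900, end_b = 10100,
                       neg_log10_p = 3)
  body_ia <- data.frame(chrom_a = "chr1", start_a = 400, end_a = 600,
                        chrom_b = "chr1", start_b = 23000, end_b = 24000,
                        neg_log10_p = 2.5)
  weak_ia <- transform(tss_ia, neg_log10_p = 1.5)
  expect_equal(score_microc(v, tss_ia, genes, cfg), 2L)
  expect_equal(score_microc(v, body_ia, genes, cfg), 1L)
  expect_equal(score_microc(v, weak_ia, genes, cfg), 0L)
  expect_equal(score_microc(v, rbind(tss_ia, body_ia), genes, cfg), 2L)
})

test_that("contact scoring is symmetric in the anchors", {
  set.seed(32)
  genes <- gene_models("g", "chr1", 5000, 9000, 5001, "+")
  for (rep in 1:10) {
    s1 <- sample(0:2000, 3)
    s2 <- sample(4000:9500, 3)
    ia <- data.frame(chrom_a = "chr1", start_a = s1, end_a = s1 + 300,
                     chrom_b = "chr1", start_b = s2, end_b = s2 + 300,
                     neg_log10_p = runif(3, 0, 5))
    sw <- data.frame(chrom_a = ia$chrom_b, start_a = ia$start_b,
                     end_a = ia$end_b, chrom_b = ia$chrom_a,
                     start_b = ia$start_a, end_b = ia$end_a,
                     neg_log10_p = ia$neg_log10_p)
    v <- mk_variants(sample(1:10000, 5))
    expect_identical(score_microc(v, ia, genes, cfg),
                     score_microc(v, sw, genes, cfg))
  }
})

test_that("scores are monotone in the underlying statistic", {
  fdr <- sort(runif(50))
  expect_true(all(diff(score_mpra(fdr, cfg)) <= 0))
  pip <- seq(0, 1, length.out = 50)
  expect_true(all(diff(score_finemap(pip, TRUE, cfg)) >= 0))
})

test_that("missing data yields 0 scores, not errors", {
  v <- mk_variants(100)
  empty_tr <- interval_track(character(), numeric(), numeric())
  expect_equal(score_peak_overlap(v, empty_tr), 0L)
  expect_warning(a <- score_akita(v, data.frame(chrom = character(),
                                                pos = numeric(),
                                                score = numeric()), cfg))
  expect_equal(a, 0L)
  no_ia <- data.frame(chrom_a = character(), start_a = numeric(),
                      end_a = numeric(), chrom_b = character(),
                      start_b = numeric(), end_b = numeric(),
                      neg_log10_p = numeric())
  genes <- gene_models("g", "chr1", 0, 10, 1, "+")
  expect_equal(score_microc(v, no_ia, genes, cfg), 0L)
  expect_equal(score_smr("v1", data.frame(variant_id = character(),
                                          gene_id = character())), 0L)
})
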