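mk_smr <- function(p_smr, p_heidi, locus = "L1", gene = "g1", variant = "v1",
                   tissue = "normal", beta = 0.3) {
  data.frame(gene_id = gene, variant_id = variant, locus_id = locus,
             tissue = tissue, p_smr = p_smr, p_heidi = p_heidi, beta = beta,
             stringsAsFactors = FALSE)
}

test_that("SMR filtering applies per-locus Bonferroni and HEIDI", {
  gpl <- c(L1 = 4L)
  expect_equal(nrow(filter_smr(mk_smr(0.01, 0.2), gpl)), 1L)  # 0.04 < 0.05
  expect_equal(nrow(filter_smr(mk_smr(0.02, 0.2), gpl)), 0L)  # 0.08
  expect_equal(nrow(filter_smr(mk_smr(0.001, 0.01), gpl)), 0L)  # HEIDI
  expect_warning(z <- filter_smr(mk_smr(0.001, 0.5, locus = "L9"), gpl),
                 "absent")
  expect_equal(nrow(z), 0L)
})

test_that("SMR filtering is monotone in both P values (property)", {
  set.seed(51)
  gpl <- c(L1 = 3L)
  for (rep in 1:50) {
    ps <- runif(1, 0, 0.1); ph <- runif(1)
    pass <- nrow(filter_smr(mk_smr(ps, ph), gpl)) == 1L
    if (pass) {
      expect_equal(nrow(filter_smr(mk_smr(ps / 2, ph), gpl)), 1L)
      expect_equal(nrow(filter_smr(mk_smr(ps, min(1, ph * 1.5)), gpl)), 1L)
    }
  }
})

test_that("the Bonferroni eQTL threshold is alpha over gene count", {
  expect_equal(eqtl_bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(eqtl_bonferroni_threshold(100, 0.05), 5e-4)
  expect_error(eqtl_bonferroni_threshold(0), ">= 1")
})

test_that("direction concordance compares harmonized signs", {
  expect_true(direction_concordance(0.8, 0.3))
  expect_false(direction_concordance(0.8, -0.3))
  expect_warning(z <- direction_concordance(0, 0.3), "zero effect")
  expect_false(z)
  # allele harmonization flips the beta when oriented to the ref allele
  b <- harmonize_effect(-0.3, "A", mpra_ref = "A", mpra_alt = "G")
  expect_equal(b, 0.3)
  expect_true(direction_concordance(0.8, b))
  expect_equal(harmonize_effect(0.4, "G", "A", "G"), 0.4)
  expect_warning(harmonize_effect(0.4, "T", "A", "G"), "neither")
})

# shared nomination fixture pieces
tiers1 <- data.frame(variant_id = c("v1", "v2", "v3"), tier = c(1L, 2L, 3L))
mem1 <- data.frame(locus_id = "L1", variant_id = c("v1", "v2", "v3"))
no_ev <- data.frame(variant_id = character(), gene_id = character(),
                    source = character())
no_body <- data.frame(variant_id = character(), gene_id = character())
vv <- mk_variants(c(150, 500, 900), id = c("v1", "v2", "v3"))
gg <- gene_models("gIntron", "chr1", 100, 300, 101, "+")

test_that("two evidence sources on a Tier 1 variant give a strong link", {
  ev <- data.frame(variant_id = "v1", gene_id = "gene1",
                   source = c("SMR_NORMAL", "MICROC_TSS"))
  ln <- nominate_genes(tiers1, mem1, ev, no_body, vv, gg)
  expect_equal(ln$status, "strong")
  expect_equal(ln$gene_id, "gene1")
  expect_equal(ln$evidence, "MICROC_TSS,SMR_NORMAL")
  expect_true(is.na(ln$fallback))
})

test_that("evidence is unioned per gene across a locus's Tier 1 variants", {
  t2 <- data.frame(variant_id = c("v1", "v2", "v3"), tier = c(1L, 1L, 3L))
  ev <- data.frame(variant_id = c("v1", "v2"), gene_id = "gene1",
                   source = c("ABC", "SMR_TUMOR"))
  ln <- nominate_genes(t2, mem1, ev, no_body, vv, gg)
  expect_equal(ln$status, "strong")
  expect_equal(ln$variant_id, "v1,v2")
})

test_that("single-source loci fall back to gene-body contacts", {
  ev <- data.frame(variant_id = "v1", gene_id = "gene1", source = "ABC")
  body <- data.frame(variant_id = "v1", gene_id = "gene2")
  ln <- nominate_genes(tiers1, mem1, ev, body, vv, gg)
  expect_equal(ln$status, "weak")
  expect_equal(ln$fallback, "microc_body")
  expect_equal(ln$gene_id, "gene2")
})

test_that("loci without Tier 1 variants retry on Tier 2, all weak", {
  t3 <- data.frame(variant_id = c("v1", "v2", "v3"), tier = c(2L, 2L, 3L))
  ev <- data.frame(variant_id = "v1", gene_id = "gene1",
                   source = c("SMR_NORMAL", "ABC"))
  ln <- nominate_genes(t3, mem1, ev, no_body, vv, gg)
  expect_equal(ln$status, "weak")
  expect_equal(ln$fallback, "tier2")
  expect_equal(ln$gene_id, "gene1")
})

test_that("the last resort is an intronic weak link, else no link at all", {
  ln <- nominate_genes(tiers1, mem1, no_ev, no_body, vv, gg)
  expect_equal(ln$status, "weak")
  expect_equal(ln$fallback, "intronic")
  expect_equal(ln$gene_id, "gIntron")  # v1 at 150 sits inside [100, 300)
  # no considered variant inside a gene: nothing is nominated
  far <- mk_variants(c(5000, 6000, 7000), id = c("v1", "v2", "v3"))
  expect_equal(nrow(nominate_genes(tiers1, mem1, no_ev, no_body, far, gg)),
               0L)
})

test_that("fallbacks only fire when earlier stages produced nothing", {
  # strong link present: body contacts and intronic must not appear
  ev <- data.frame(variant_id = "v1", gene_id = "gene1",
                   source = c("SMR_NORMAL", "MICROC_TSS"))
  body <- data.frame(variant_id = "v1", gene_id = "gene2")
  ln <- nominate_genes(tiers1, mem1, ev, body, vv, gg)
  expect_equal(ln$gene_id, "gene1")
  expect_false("gene2" %in% ln$gene_id)
  expect_false("gIntron" %in% ln$gene_id)
})

test_that("nomination is invariant to evidence row order and never cites a
           source twice", {
  set.seed(52)
  ev <- data.frame(variant_id = c("v1", "v1", "v1", "v2"),
                   gene_id = c("gene1", "gene1", "gene1", "gene1"),
                   source = c("SMR_NORMAL", "SMR_NORMAL", "ABC",
                              "MICROC_TSS"))
  t2 <- data.frame(variant_id = c("v1", "v2", "v3"), tier = c(1L, 1L, 2L))
  base <- nominate_genes(t2, mem1, ev, no_body, vv, gg)
  for (rep in 1:5) {
    sh <- ev[sample(nrow(ev)), ]
    expect_identical(nominate_genes(t2, mem1, sh, no_body, vv, gg), base)
  }
  srcs <- strsplit(base$evidence, ",")[[1]]
  expect_equal(anyDuplicated(srcs), 0L)
  expect_gte(length(srcs), 2L)
})
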