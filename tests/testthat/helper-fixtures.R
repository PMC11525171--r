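# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write.

# write tab-joined lines to a temp file and return its path
write_track_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a minimal variant table at given positions on one chromosome
mk_variants <- function(pos, id = sprintf("v%02d", seq_along(pos)),
                        chrom = "chr1", p = NA_real_, r2 = NA_real_) {
  variant_table(id = id, chrom = chrom, pos = pos, gwas_p = p,
                r2_to_lead = r2)
}

# brute-force credible-set oracle: smallest qualifying prefix of the
# PIP-descending (id-tiebroken) ordering
oracle_credible_set <- function(records, coverage = 0.95, min_pip = 0.001) {
  el <- records[records$pip > min_pip, , drop = FALSE]
  if (!nrow(el)) return(character())
  el <- el[order(-el$pip, el$variant_id), , drop = FALSE]
  for (k in seq_len(nrow(el))) {
    if (sum(el$pip[seq_len(k)]) >= coverage) return(el$variant_id[seq_len(k)])
  }
  el$variant_id
}

# exact binomial upper-tail oracle via term-by-term enumeration
oracle_binom_tail <- function(k, n, p0) {
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# rank-based separation (AUC) of causal vs background totals
auc_separation <- function(causal_scores, background_scores) {
  n1 <- length(causal_scores); n2 <- length(background_scores)
  r <- rank(c(causal_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
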