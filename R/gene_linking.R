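# SMR filtering, MPRA/eQTL direction concordance and effector-gene
# nomination from tiered variants.

#' Filter SMR results by per-locus Bonferroni and HEIDI
#'
#' A record passes iff `p_smr * genes_per_locus[locus] < 0.05` (Bonferroni
#' correction by the number of genes at its risk locus) and
#' `p_heidi > 0.05` (heterogeneity test does not indicate linkage).
#' Records whose locus is missing from the count map are rejected with a
#' warning.
#'
#' @param records data.frame (gene_id, variant_id, locus_id, tissue, p_smr,
#'   p_heidi, beta) with tissue in {"normal", "tumor"}.
#' @param genes_per_locus named integer vector, locus_id -> gene count
#'   (>= 1).
#' @param alpha family-wise error target (default 0.05).
#' @param heidi_min HEIDI floor, strict (default 0.05).
#' @return the passing rows of `records`.
#' @export
filter_smr <- function(records, genes_per_locus, alpha = 0.05,
                       heidi_min = 0.05) {
  if (!nrow(records)) return(records)
  if (any(genes_per_locus < 1))
    stop("genes_per_locus must be >= 1", call. = FALSE)
  ng <- genes_per_locus[records$locus_id]
  missing <- is.na(ng)
  if (any(missing))
    warning(sum(missing), " SMR record(s) at loci absent from the gene-count map; rejected",
            call. = FALSE)
  pass <- !missing & records$p_smr * ng < alpha & records$p_heidi > heidi_min
  out <- records[pass, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Bonferroni-corrected eQTL significance threshold
#'
#' The global threshold for calling an eQTL significant when `n_genes`
#' genes were tested: `alpha / n_genes`.
#'
#' @param n_genes number of unique genes tested (>= 1).
#' @param alpha family-wise error target (default 0.05).
#' @return the corrected P-value threshold.
#' @export
eqtl_bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1)
    stop("n_genes must be a single integer >= 1", call. = FALSE)
  alpha / n_genes
}

#' Harmonize an eQTL effect to the MPRA alt allele
#'
#' Flips the eQTL beta when its effect allele equals the MPRA reference
#' allele, so both effects are oriented to the alternative allele.
#'
#' @param beta eQTL effect size(s).
#' @param eqtl_effect_allele allele the eQTL beta refers to.
#' @param mpra_ref,mpra_alt MPRA reference and alternative alleles.
#' @return harmonized beta; NA (with a warning) when the effect allele
#'   matches neither MPRA allele.
#' @export
harmonize_effect <- function(beta, eqtl_effect_allele, mpra_ref, mpra_alt) {
  out <- ifelse(eqtl_effect_allele == mpra_alt, beta,
                ifelse(eqtl_effect_allele == mpra_ref, -beta, NA_real_))
  if (anyNA(out))
    warning("eQTL effect allele matches neither MPRA allele for ",
            sum(is.na(out)), " record(s)", call. = FALSE)
  out
}

#' Direction concordance between MPRA and eQTL effects
#'
#' TRUE iff the MPRA allelic log-ratio and the (harmonized) eQTL beta have
#' the same nonzero sign. A zero effect on either side gives FALSE with a
#' warning.
#'
#' @param log_ratio MPRA alt-vs-ref allelic activity log-ratio.
#' @param beta eQTL effect of the alt allele (see [harmonize_effect()]).
#' @return logical vector.
#' @export
direction_concordance <- function(log_ratio, beta) {
  len <- max(length(log_ratio), length(beta))
  log_ratio <- rep_len(log_ratio, len)
  beta <- rep_len(beta, len)
  zero <- !is.na(log_ratio) & !is.na(beta) & (log_ratio == 0 | beta == 0)
  if (any(zero))
    warning(sum(zero), " record(s) with a zero effect; concordance FALSE",
            call. = FALSE)
  !is.na(log_ratio) & !is.na(beta) & log_ratio != 0 & beta != 0 &
    sign(log_ratio) == sign(beta)
}

#' Nominate effector genes per locus from tiered variants
#'
#' Per locus, in order: (1) union the evidence sources (SMR_NORMAL,
#' SMR_TUMOR, ABC, MICROC_TSS) per gene across the locus's Tier 1 variants;
#' genes backed by at least two distinct sources become strong links.
#' (2) If no gene qualifies, chromatin contacts of Tier 1 variants into
#' gene bodies yield weak links (fallback "microc_body"). (3) If the locus
#' has no Tier 1 variants at all, stages 1-2 are repeated on its Tier 2
#' variants, and every resulting link is weak (fallback "tier2").
#' (4) If still nothing and a considered variant lies inside a gene body,
#' that gene is a weak link (fallback "intronic"; without an exon table
#' "intronic" degrades to gene-body containment). A locus exhausting all
#' stages yields no link, which is a legitimate outcome.
#'
#' @param tiers data.frame (variant_id, tier) from [assign_tiers()].
#' @param membership data.frame (locus_id, variant_id) mapping candidate
#'   variants to loci.
#' @param evidence data.frame (variant_id, gene_id, source) with source in
#'   {"SMR_NORMAL", "SMR_TUMOR", "ABC", "MICROC_TSS"}.
#' @param microc_body data.frame (variant_id, gene_id) of gene-body
#'   chromatin contacts.
#' @param variants data.frame (id, chrom, pos) for the intronic fallback.
#' @param genes gene-model data.frame.
#' @return data.frame (locus_id, gene_id, variant_id, evidence, status,
#'   fallback); `evidence` is a comma-joined sorted source set, `status` is
#'   "strong" or "weak", `fallback` is NA for strong links.
#' @export
nominate_genes <- function(tiers, membership, evidence, microc_body,
                           variants, genes) {
  stopifnot(all(c("variant_id", "tier") %in% names(tiers)))
  ev_sources <- c("SMR_NORMAL", "SMR_TUMOR", "ABC", "MICROC_TSS")
  if (nrow(evidence) && !all(evidence$source %in% ev_sources))
    stop("unknown evidence source(s): ",
         paste(setdiff(unique(evidence$source), ev_sources), collapse = ", "),
         call. = FALSE)
  link_row <- function(locus, gene, vars, ev, status, fallback) {
    data.frame(locus_id = locus, gene_id = gene,
               variant_id = paste(sort(unique(vars)), collapse = ","),
               evidence = paste(sort(unique(ev)), collapse = ","),
               status = status, fallback = fallback,
               stringsAsFactors = FALSE)
  }
  evidence_stage <- function(locus, vset) {
    ev <- evidence[evidence$variant_id %in% vset, , drop = FALSE]
    ev <- unique(ev)
    if (!nrow(ev)) return(NULL)
    rows <- lapply(sort(unique(ev$gene_id)), function(g) {
      sub <- ev[ev$gene_id == g, , drop = FALSE]
      if (length(unique(sub$source)) >= 2L)
        link_row(locus, g, sub$variant_id, sub$source, "strong", NA_character_)
    })
    do.call(rbind, rows)
  }
  body_stage <- function(locus, vset, fb) {
    mb <- unique(microc_body[microc_body$variant_id %in% vset, , drop = FALSE])
    if (!nrow(mb)) return(NULL)
    rows <- lapply(sort(unique(mb$gene_id)), function(g)
      link_row(locus, g, mb$variant_id[mb$gene_id == g], "MICROC_BODY",
               "weak", fb))
    do.call(rbind, rows)
  }
  intronic_stage <- function(locus, vset) {
    vv <- variants[variants$id %in% vset, , drop = FALSE]
    if (!nrow(vv) || !nrow(genes)) return(NULL)
    rows <- list()
    for (i in seq_len(nrow(vv))) {
      g <- genes[genes$chrom == vv$chrom[i] &
                   variant_in_interval(vv$pos[i], genes$start, genes$end), ,
                 drop = FALSE]
      for (gid in g$gene_id)
        rows[[length(rows) + 1L]] <-
          link_row(locus, gid, vv$id[i], "INTRONIC", "weak", "intronic")
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  tier_of <- stats::setNames(tiers$tier, tiers$variant_id)
  out <- list()
  for (locus in sort(unique(membership$locus_id))) {
    vset_all <- membership$variant_id[membership$locus_id == locus]
    v1 <- vset_all[tier_of[vset_all] %in% 1L]
    v2 <- vset_all[tier_of[vset_all] %in% 2L]
    links <- NULL
    if (length(v1)) {
      links <- evidence_stage(locus, v1)
      if (is.null(links)) links <- body_stage(locus, v1, "microc_body")
      considered <- v1
    } else {
      if (length(v2)) {
        links <- evidence_stage(locus, v2)
        if (is.null(links)) links <- body_stage(locus, v2, "microc_body")
        if (!is.null(links)) {
          links$status <- "weak"
          links$fallback <- "tier2"
        }
      }
      considered <- v2
    }
    if (is.null(links) && length(considered))
      links <- intronic_stage(locus, considered)
    if (!is.null(links)) out[[locus]] <- links
  }
  if (!length(out))
    return(data.frame(locus_id = character(), gene_id = character(),
                      variant_id = character(), evidence = character(),
                      status = character(), fallback = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  row.names(res) <- NULL
  res
}
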