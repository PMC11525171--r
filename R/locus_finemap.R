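# Risk-locus definition, candidate-variant selection and credible sets.

#' Define risk loci by greedy distance clumping
#'
#' Variants with `gwas_p < p_threshold` are sorted by ascending P; a variant
#' becomes a locus lead iff it lies at least `min_separation_bp` from every
#' previously accepted lead on the same chromosome. Each locus spans
#' lead +/- `window_bp`.
#'
#' @param stats variant data.frame (see [variant_table()]); needs id, chrom,
#'   pos, gwas_p.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param min_separation_bp minimum lead separation (default 500000).
#' @param window_bp locus half-window around the lead (default 250000).
#' @return data.frame (locus_id, lead_id, chrom, lead_pos, lead_p,
#'   window_start, window_end) with 0-based half-open windows, ordered by
#'   lead significance. No qualifying variant gives zero rows.
#' @export
define_loci <- function(stats, p_threshold = 5e-8, min_separation_bp = 500000L,
                        window_bp = 250000L) {
  if (!nrow(stats)) stop("stats must be non-empty", call. = FALSE)
  qual <- stats[!is.na(stats$gwas_p) & stats$gwas_p < p_threshold, , drop = FALSE]
  empty <- data.frame(locus_id = character(), lead_id = character(),
                      chrom = character(), lead_pos = integer(),
                      lead_p = numeric(), window_start = numeric(),
                      window_end = numeric(), stringsAsFactors = FALSE)
  if (!nrow(qual)) return(empty)
  # ties in P broken by id for determinism
  qual <- qual[order(qual$gwas_p, qual$id, method = "radix"), , drop = FALSE]
  lead_idx <- integer()
  for (i in seq_len(nrow(qual))) {
    if (length(lead_idx)) {
      same <- qual$chrom[lead_idx] == qual$chrom[i]
      if (any(same) &&
          any(abs(qual$pos[lead_idx][same] - qual$pos[i]) < min_separation_bp))
        next
    }
    lead_idx <- c(lead_idx, i)
  }
  leads <- qual[lead_idx, , drop = FALSE]
  data.frame(locus_id = sprintf("L%03d", seq_len(nrow(leads))),
             lead_id = leads$id, chrom = leads$chrom, lead_pos = leads$pos,
             lead_p = leads$gwas_p,
             window_start = pmax(0, leads$pos - 1 - window_bp),
             window_end = leads$pos - 1 + window_bp + 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign variants to locus windows
#'
#' A variant is a member of every locus whose window contains it (windows of
#' nearby loci may overlap).
#'
#' @param stats variant data.frame.
#' @param loci locus table from [define_loci()].
#' @return data.frame (locus_id, variant_id, is_lead) in locus order.
#' @export
locus_members <- function(stats, loci) {
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    inw <- stats$chrom == loci$chrom[i] &
      variant_in_interval(stats$pos, loci$window_start[i], loci$window_end[i])
    out[[i]] <- data.frame(locus_id = loci$locus_id[i],
                           variant_id = stats$id[inw],
                           is_lead = stats$id[inw] == loci$lead_id[i],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Select candidate variants of a locus for functional testing
#'
#' Two inclusion rules, applied to locus members:
#' rule 1 keeps variants whose P is within three orders of magnitude of the
#' lead (`gwas_p <= 1000 * lead_p`, boundary inclusive); rule 2 keeps
#' variants with `-log10(P) > 0.7 * -log10(P_lead)`, `r2_to_lead > 0.2` and
#' `gwas_p < 1e-5`. Variants with missing r2 are only eligible via rule 1.
#' The lead is always selected.
#'
#' @param members variant data.frame of one locus (id, gwas_p, r2_to_lead).
#' @param lead_id id of the locus lead (must be among members).
#' @param ratio_max rule-1 bound on `gwas_p / lead_p` (default 1000).
#' @param log_frac rule-2 fraction of the lead's -log10 P (default 0.7).
#' @param r2_min rule-2 LD floor (default 0.2, strict).
#' @param p_max rule-2 significance cap (default 1e-5, strict).
#' @return `members` rows that are selected, with a `selection_rule` column
#'   ("lead", "within_3oom" or "ld_rule").
#' @export
select_candidate_variants <- function(members, lead_id, ratio_max = 1000,
                                      log_frac = 0.7, r2_min = 0.2,
                                      p_max = 1e-5) {
  if (!lead_id %in% members$id)
    stop("lead ", lead_id, " not among locus members", call. = FALSE)
  lead_p <- members$gwas_p[members$id == lead_id][1]
  p <- members$gwas_p
  # tiny relative tolerance so the inclusive boundary survives binary rounding
  rule1 <- !is.na(p) & p <= ratio_max * lead_p * (1 + 1e-12)
  r2 <- members$r2_to_lead
  rule2 <- !is.na(p) & !is.na(r2) &
    (-log10(p) > log_frac * (-log10(lead_p))) & r2 > r2_min & p < p_max
  keep <- rule1 | rule2 | members$id == lead_id
  out <- members[keep, , drop = FALSE]
  out$selection_rule <- ifelse(out$id == lead_id, "lead",
                               ifelse(rule1[keep], "within_3oom", "ld_rule"))
  row.names(out) <- NULL
  out
}

#' Construct a credible set from posterior inclusion probabilities
#'
#' Variants with `pip > min_pip` are ranked by descending PIP (ties broken
#' by variant id for determinism) and included until the cumulative PIP
#' reaches `coverage`, including the variant that crosses the threshold.
#' If the total eligible mass is below `coverage`, all eligible variants are
#' included.
#'
#' @param records data.frame (variant_id, pip).
#' @param coverage cumulative-PIP target (default 0.95).
#' @param min_pip individual PIP floor, strict (default 0.001).
#' @return character vector of included variant ids (possibly empty).
#' @export
build_credible_set <- function(records, coverage = 0.95, min_pip = 0.001) {
  if (!nrow(records)) return(character())
  if (any(records$pip < 0 | records$pip > 1, na.rm = TRUE))
    stop("PIPs must lie in [0, 1]", call. = FALSE)
  el <- records[!is.na(records$pip) & records$pip > min_pip, , drop = FALSE]
  if (!nrow(el)) return(character())
  el <- el[order(-el$pip, el$variant_id, method = "radix"), , drop = FALSE]
  cum <- cumsum(el$pip)
  k <- if (cum[nrow(el)] < coverage) nrow(el) else which(cum >= coverage)[1]
  el$variant_id[seq_len(k)]
}
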