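# Cross-cell-line consensus, score summation and tier assignment.

#' Strict-majority consensus of per-cell-line scores
#'
#' Level-wise rule for ATAC, CTCF, chromatin-contact and chromatin-state
#' terms: a level L in {2, 1} is retained iff strictly more than half of
#' the cell lines with data score at least L; the consensus is the highest
#' retained level, else 0. NA entries mean "no data for this cell line" and
#' are excluded from the denominator; an empty denominator gives 0 with a
#' warning.
#'
#' @param values integer scores in 0:2, one per cell line (NA = no data).
#' @return list with `value` (consensus score), `n_cell_lines`
#'   (denominator) and `n_supporting` (cell lines scoring >= the consensus
#'   level, 0 when the consensus is 0).
#' @export
majority_consensus <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0L) {
    warning("no cell line with data; consensus 0", call. = FALSE)
    return(list(value = 0L, n_cell_lines = 0L, n_supporting = 0L))
  }
  for (L in c(2L, 1L)) {
    k <- sum(v >= L)
    if (k > n / 2) return(list(value = L, n_cell_lines = n, n_supporting = k))
  }
  list(value = 0L, n_cell_lines = n, n_supporting = 0L)
}

#' Binomial survival-function consensus
#'
#' Given k cell lines (of n with data) flagging a variant as "score in the
#' 90th percentile", computes the upper-tail probability
#' P = Pr(X >= k), X ~ Binomial(n, p0). Score 2 iff P < 0.01, 1 iff
#' P < 0.05, else 0. k = 0 short-circuits to 0 (no evidence cannot signal
#' enrichment), as does n = 0.
#'
#' @param k number of flagged cell lines (vectorized).
#' @param n number of cell lines with data (vectorized).
#' @param p0 null flag probability (default 0.10).
#' @return integer scores in 0:2.
#' @export
binomial_consensus <- function(k, n, p0 = 0.10) {
  len <- max(length(k), length(n))
  k <- rep_len(as.integer(k), len)
  n <- rep_len(as.integer(n), len)
  out <- integer(len)
  act <- k >= 1L & n >= 1L
  if (any(act)) {
    p <- stats::pbinom(k[act] - 1L, n[act], p0, lower.tail = FALSE)
    out[act] <- ifelse(p < 0.01, 2L, ifelse(p < 0.05, 1L, 0L))
  }
  out
}

#' 90th-percentile hit flags per cell line
#'
#' For analyses whose native output is a continuous score (ABC scores, TF
#' motif match scores): within each cell line, an item is flagged iff its
#' best score is at or above the 90th-percentile value of all that cell
#' line's scores (inclusive boundary). Items absent from a cell line get no
#' flag there (excluded from the binomial n).
#'
#' @param score_tables named list (cell line -> data.frame(item_id, score)).
#' @param prob flag quantile (default 0.90).
#' @return data.frame (item_id, cell_line, flag).
#' @export
percentile_hit_flags <- function(score_tables, prob = 0.90) {
  out <- lapply(names(score_tables), function(cl) {
    tab <- score_tables[[cl]]
    if (is.null(tab) || !nrow(tab))
      return(data.frame(item_id = character(), cell_line = character(),
                        flag = logical(), stringsAsFactors = FALSE))
    q <- stats::quantile(tab$score, prob, names = FALSE, na.rm = TRUE)
    best <- tapply(tab$score, tab$item_id, max)
    data.frame(item_id = names(best), cell_line = cl,
               flag = unname(best) >= q, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sum per-term scores into a total per variant
#'
#' Missing terms contribute 0. Every term must appear at most once per
#' variant after consensus, except the MPRA term which contributes one
#' summand per assayed cell line (encode them as distinct terms, e.g.
#' "MPRA_HT29").
#'
#' @param term_scores data.frame (variant_id, term, value).
#' @return data.frame (variant_id, total_score) sorted by variant_id.
#' @export
sum_scores <- function(term_scores) {
  dup <- duplicated(term_scores[c("variant_id", "term")])
  if (any(dup))
    stop("duplicated (variant, term) pairs: ",
         paste(utils::head(term_scores$variant_id[dup], 3), collapse = ", "),
         call. = FALSE)
  tot <- tapply(term_scores$value, term_scores$variant_id, sum)
  data.frame(variant_id = names(tot), total_score = as.integer(unname(tot)),
             stringsAsFactors = FALSE)[order(names(tot), method = "radix"), ,
                                       drop = FALSE] -> out
  row.names(out) <- NULL
  out
}

#' Assign Tier 1/2/3 from total scores
#'
#' Variants are ranked globally by descending total score (ties broken by
#' id only for output order, never for the tier itself). The top
#' `ceiling(0.2 N)` positions are Tier 1, positions down to
#' `N - floor(0.5 N)` are Tier 2, the bottom `floor(0.5 N)` are Tier 3.
#' Variants whose score ties across a boundary are all promoted to the
#' better tier, so tiers are a deterministic function of the score alone.
#'
#' @param totals data.frame (variant_id, total_score).
#' @param top_frac Tier-1 band (default 0.20).
#' @param bottom_frac Tier-3 band (default 0.50).
#' @return data.frame (variant_id, total_score, rank, rank_percentile,
#'   tier); `rank_percentile` is the fraction of variants scoring strictly
#'   higher (0 = best).
#' @export
assign_tiers <- function(totals, top_frac = 0.20, bottom_frac = 0.50) {
  n <- nrow(totals)
  if (!n) stop("totals must be non-empty", call. = FALSE)
  o <- order(-totals$total_score, totals$variant_id, method = "radix")
  sc <- totals$total_score[o]
  pos <- seq_len(n)
  b1 <- ceiling(top_frac * n)
  b2 <- n - floor(bottom_frac * n)
  tier_pos <- ifelse(pos <= b1, 1L, ifelse(pos <= b2, 2L, 3L))
  # tie promotion: every variant takes the best tier reached by its score
  tier <- stats::ave(tier_pos, sc, FUN = min)
  pct <- vapply(sc, function(s) sum(sc > s), numeric(1)) / n
  out <- data.frame(variant_id = totals$variant_id[o], total_score = sc,
                    rank = pos, rank_percentile = pct, tier = as.integer(tier),
                    stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}
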