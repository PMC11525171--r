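# Per-variant, per-annotation 0/1/2 scoring.
#
# Terms: MPRA (one summand per assayed cell line), FINEMAP, CHROMHMM, ATAC,
# CTCF, MICROC (cell-line-resolved, collapsed by majority consensus),
# SMR_NORMAL, SMR_TUMOR, AKITA (single summands), plus ABC and TF which are
# collapsed by the binomial consensus (see consensus_tiering.R).

#' Default chromatin-state score map
#'
#' Promoter/enhancer states score 2, weak or flanking states score 1,
#' everything else 0. The exact membership of the "weak" set is a modeling
#' choice (state labels differ between segmentation models), so the map is
#' configuration, not hard-coded truth: pass your own named vector to
#' [scoring_config()] to override.
#'
#' @return named integer vector mapping state label to score.
#' @export
chromhmm_default_state_map <- function() {
  c(TssA = 2L, Enh = 2L, EnhG = 2L,
    TssAFlnk = 1L, TssFlnk = 1L, TxFlnk = 1L, EnhWk = 1L, EnhBiv = 1L,
    TssBiv = 1L, TxWk = 1L,
    Tx = 0L, ZNF_Rpts = 0L, Het = 0L, ReprPC = 0L, ReprPCWk = 0L, Quies = 0L)
}

#' Scoring configuration
#'
#' Thresholds for every annotation rule. Strong thresholds must be stricter
#' than hit thresholds.
#'
#' @param mpra_fdr_strong MPRA FDR for a strong hit (score 2), default 1e-3.
#' @param mpra_fdr_hit MPRA FDR for a hit (score 1), default 0.05.
#' @param pip_strong PIP above which fine-mapping scores 2, default 0.5.
#' @param finemap_literal_pip if TRUE, the score-1 level uses the literal
#'   `PIP > 0` reading instead of credible-set membership (default FALSE).
#' @param chromhmm_state_map named vector state label -> score in 0:2.
#' @param akita_window_bp half-window around the variant (default 100).
#' @param akita_frac fraction of window positions that must be extreme,
#'   strict (default 0.25).
#' @param akita_top_strong,akita_top_hit top quantile fractions defining
#'   "extreme" for scores 2 and 1 (defaults 0.10 and 0.20).
#' @param microc_min_neg_log10_p significance filter for chromatin contacts
#'   (default 2, i.e. -log10 P >= 2).
#' @param consensus_p0 null per-cell-line hit probability of the binomial
#'   consensus (default 0.10, matching the 90th-percentile flag rule).
#' @param tss_pad widen the TSS point by this many bp on each side when
#'   testing anchor containment (default 0).
#' @return list of class "scoring_config".
#' @export
scoring_config <- function(mpra_fdr_strong = 1e-3, mpra_fdr_hit = 0.05,
                           pip_strong = 0.5, finemap_literal_pip = FALSE,
                           chromhmm_state_map = chromhmm_default_state_map(),
                           akita_window_bp = 100L, akita_frac = 0.25,
                           akita_top_strong = 0.10, akita_top_hit = 0.20,
                           microc_min_neg_log10_p = 2,
                           consensus_p0 = 0.10, tss_pad = 0L) {
  if (mpra_fdr_strong > mpra_fdr_hit)
    stop("mpra_fdr_strong must be <= mpra_fdr_hit", call. = FALSE)
  if (akita_top_strong > akita_top_hit)
    stop("akita_top_strong must be <= akita_top_hit", call. = FALSE)
  if (!all(chromhmm_state_map %in% 0:2))
    stop("chromhmm_state_map values must be in 0:2", call. = FALSE)
  structure(list(mpra_fdr_strong = mpra_fdr_strong,
                 mpra_fdr_hit = mpra_fdr_hit, pip_strong = pip_strong,
                 finemap_literal_pip = finemap_literal_pip,
                 chromhmm_state_map = chromhmm_state_map,
                 akita_window_bp = as.integer(akita_window_bp),
                 akita_frac = akita_frac,
                 akita_top_strong = akita_top_strong,
                 akita_top_hit = akita_top_hit,
                 microc_min_neg_log10_p = microc_min_neg_log10_p,
                 consensus_p0 = consensus_p0, tss_pad = as.integer(tss_pad)),
            class = "scoring_config")
}

#' MPRA allelic-activity score
#'
#' 2 iff `fdr <= mpra_fdr_strong`; 1 iff it is at most `mpra_fdr_hit`
#' (boundaries inclusive); else 0. One score per (variant, cell line);
#' missing FDRs score 0.
#'
#' @param fdr numeric FDR vector.
#' @param cfg [scoring_config()].
#' @return integer scores in 0:2.
#' @export
score_mpra <- function(fdr, cfg = scoring_config()) {
  out <- integer(length(fdr))
  out[!is.na(fdr) & fdr <= cfg$mpra_fdr_hit] <- 1L
  out[!is.na(fdr) & fdr <= cfg$mpra_fdr_strong] <- 2L
  out
}

#' Fine-mapping score
#'
#' 2 iff `pip > pip_strong`; otherwise 1 iff the variant belongs to a
#' credible set (or, with `finemap_literal_pip = TRUE`, iff `pip > 0`);
#' else 0.
#'
#' @param pip numeric PIP vector (NA treated as 0).
#' @param in_set logical credible-set membership (recycled).
#' @param cfg [scoring_config()].
#' @return integer scores in 0:2.
#' @export
score_finemap <- function(pip, in_set, cfg = scoring_config()) {
  n <- max(length(pip), length(in_set))
  pip <- rep_len(ifelse(is.na(pip), 0, pip), n)
  in_set <- rep_len(in_set %in% TRUE, n)
  hit1 <- if (cfg$finemap_literal_pip) pip > 0 else in_set
  ifelse(pip > cfg$pip_strong, 2L, ifelse(hit1, 1L, 0L))
}

#' Chromatin-state score
#'
#' The score of the state segment containing the variant, via the
#' configured state map; 0 (with a warning) for uncovered positions and 0
#' for unmapped labels.
#'
#' @param variants data.frame with chrom, pos.
#' @param segmentation labelled interval track for one cell line.
#' @param cfg [scoring_config()].
#' @return integer scores in 0:2.
#' @export
score_chromhmm <- function(variants, segmentation, cfg = scoring_config()) {
  lab <- segment_label_at(variants$chrom, variants$pos, segmentation)
  if (anyNA(lab))
    warning(sum(is.na(lab)), " variant(s) not covered by any state segment; scored 0",
            call. = FALSE)
  val <- unname(cfg$chromhmm_state_map[lab])
  as.integer(ifelse(is.na(val), 0L, val))
}

#' Peak-overlap score (ATAC or CTCF)
#'
#' 2 iff the variant falls inside any peak; 0 otherwise. This term never
#' yields 1.
#'
#' @param variants data.frame with chrom, pos.
#' @param peaks interval track for one cell line.
#' @return integer scores in {0, 2}.
#' @export
score_peak_overlap <- function(variants, peaks) {
  2L * points_in_any_interval(variants$chrom, variants$pos, peaks)
}

#' SMR association score
#'
#' 2 iff the variant participates in at least one filter-passing SMR link
#' for the given tissue; else 0.
#'
#' @param variant_id character vector of variants to score.
#' @param passing_links data.frame of passing links (variant_id, gene_id),
#'   e.g. one tissue's rows from [filter_smr()].
#' @return integer scores in {0, 2}.
#' @export
score_smr <- function(variant_id, passing_links) {
  2L * (variant_id %in% passing_links$variant_id)
}

#' 3D-disruption (in-silico mutagenesis) score
#'
#' Let W be the scored positions within `akita_window_bp` of the variant
#' (inclusive) and q90/q80 the global `1 - akita_top_strong` /
#' `1 - akita_top_hit` quantiles of all scores in the track. Score 2 iff
#' the fraction of W at or above q90 exceeds `akita_frac`; else 1 iff the
#' q80 fraction does; else 0. Empty windows score 0 with a warning.
#'
#' @param variants data.frame with chrom, pos.
#' @param track data.frame (chrom, pos, score), positions 1-based.
#' @param cfg [scoring_config()].
#' @return integer scores in 0:2.
#' @export
score_akita <- function(variants, track, cfg = scoring_config()) {
  n <- nrow(variants)
  out <- integer(n)
  if (!nrow(track)) {
    if (n) warning("empty disruption track; all variants scored 0", call. = FALSE)
    return(out)
  }
  q_strong <- stats::quantile(track$score, 1 - cfg$akita_top_strong,
                              names = FALSE, na.rm = TRUE)
  q_hit <- stats::quantile(track$score, 1 - cfg$akita_top_hit,
                           names = FALSE, na.rm = TRUE)
  w <- cfg$akita_window_bp
  n_empty <- 0L
  for (ch in unique(variants$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    sel <- which(variants$chrom == ch)
    if (!nrow(tr)) { n_empty <- n_empty + length(sel); next }
    o <- order(tr$pos)
    tp <- tr$pos[o]; ts <- tr$score[o]
    for (i in sel) {
      lo <- findInterval(variants$pos[i] - w - 1L, tp) + 1L
      hi <- findInterval(variants$pos[i] + w, tp)
      if (hi < lo) { n_empty <- n_empty + 1L; next }
      ws <- ts[lo:hi]
      if (mean(ws >= q_strong) > cfg$akita_frac) out[i] <- 2L
      else if (mean(ws >= q_hit) > cfg$akita_frac) out[i] <- 1L
    }
  }
  if (n_empty)
    warning(n_empty, " variant(s) with no scored positions in the window; scored 0",
            call. = FALSE)
  out
}

#' Enumerate significant chromatin contacts anchored on variants
#'
#' For every interaction with `neg_log10_p >= microc_min_neg_log10_p` and a
#' variant inside one anchor, classifies the distal anchor: "tss" if it
#' contains a gene's TSS point (padded by `tss_pad`), "body" if it overlaps
#' a gene body. Symmetric in the two anchors.
#'
#' @param variants data.frame with id, chrom, pos.
#' @param interactions interaction data.frame (see
#'   [load_interaction_track()]).
#' @param genes gene-model data.frame (see [gene_models()]).
#' @param cfg [scoring_config()].
#' @return data.frame (variant_id, gene_id, contact) with contact in
#'   {"tss", "body"}; zero rows when nothing qualifies.
#' @export
microc_gene_contacts <- function(variants, interactions, genes,
                                 cfg = scoring_config()) {
  empty <- data.frame(variant_id = character(), gene_id = character(),
                      contact = character(), stringsAsFactors = FALSE)
  if (!nrow(interactions) || !nrow(variants) || !nrow(genes)) return(empty)
  ia <- interactions[interactions$neg_log10_p >= cfg$microc_min_neg_log10_p, ,
                     drop = FALSE]
  if (!nrow(ia)) return(empty)
  # double the table so each anchor plays the "variant side" once
  dbl <- data.frame(
    chrom_v = c(ia$chrom_a, ia$chrom_b),
    start_v = c(ia$start_a, ia$start_b), end_v = c(ia$end_a, ia$end_b),
    chrom_d = c(ia$chrom_b, ia$chrom_a),
    start_d = c(ia$start_b, ia$start_a), end_d = c(ia$end_b, ia$end_a),
    stringsAsFactors = FALSE)
  pad <- cfg$tss_pad
  res <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    inv <- dbl$chrom_v == variants$chrom[i] &
      variant_in_interval(variants$pos[i], dbl$start_v, dbl$end_v)
    if (!any(inv)) next
    d <- dbl[inv, , drop = FALSE]
    hits <- vector("list", nrow(d))
    for (j in seq_len(nrow(d))) {
      g <- genes[genes$chrom == d$chrom_d[j], , drop = FALSE]
      if (!nrow(g)) next
      tss_in <- (g$tss_pos - 1) >= (d$start_d[j] - pad) &
        (g$tss_pos - 1) < (d$end_d[j] + pad)
      body_in <- g$start < d$end_d[j] & d$start_d[j] < g$end
      if (any(tss_in) || any(body_in))
        hits[[j]] <- data.frame(
          variant_id = variants$id[i],
          gene_id = c(g$gene_id[tss_in], g$gene_id[body_in & !tss_in]),
          contact = c(rep("tss", sum(tss_in)),
                      rep("body", sum(body_in & !tss_in))),
          stringsAsFactors = FALSE)
    }
    res[[i]] <- do.call(rbind, hits)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  unique(out)
}

#' Long-range chromatin-contact score
#'
#' Over all qualifying contacts anchored on the variant: 2 if any distal
#' anchor contains a gene TSS; else 1 if any distal anchor overlaps a gene
#' body; else 0.
#'
#' @inheritParams microc_gene_contacts
#' @return integer scores in 0:2, one per variant row.
#' @export
score_microc <- function(variants, interactions, genes,
                         cfg = scoring_config()) {
  contacts <- microc_gene_contacts(variants, interactions, genes, cfg)
  vapply(variants$id, function(v) {
    cc <- contacts$contact[contacts$variant_id == v]
    if (any(cc == "tss")) 2L else if (any(cc == "body")) 1L else 0L
  }, integer(1), USE.NAMES = FALSE)
}
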