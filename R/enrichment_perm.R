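# Permutation enrichment: associated-variant-set (AVS) overlap with peaks,
# and transcription-factor binding counts over GWAS regions.

#' Build associated variant sets (AVS) from locus LD
#'
#' Per locus, members with `r2_to_lead >= 0.8` and `dprime_to_lead >= 0.8`
#' (both inclusive, both required); the lead is always included.
#'
#' @param members data.frame (locus_id, variant_id, chrom, pos, is_lead,
#'   r2_to_lead, dprime_to_lead).
#' @param r2_min,dprime_min inclusive LD thresholds (defaults 0.8).
#' @return data.frame (locus_id, variant_id, chrom, pos); every locus keeps
#'   at least its lead (AVS of size 1).
#' @export
build_avs <- function(members, r2_min = 0.8, dprime_min = 0.8) {
  keep <- members$is_lead %in% TRUE |
    (!is.na(members$r2_to_lead) & !is.na(members$dprime_to_lead) &
       members$r2_to_lead >= r2_min & members$dprime_to_lead >= dprime_min)
  out <- members[keep, c("locus_id", "variant_id", "chrom", "pos")]
  row.names(out) <- NULL
  out
}

#' Empirical p-value from null tallies
#' @noRd
.empirical_p <- function(observed, null_tallies, smooth) {
  n <- length(null_tallies)
  hits <- sum(null_tallies >= observed)
  if (smooth) (hits + 1) / (n + 1) else hits / n
}

#' AVS / peak permutation enrichment
#'
#' The observed tally counts AVS with at least one member inside a peak
#' (`tally = "loci"`, the variant-set-enrichment convention) or the total
#' number of overlapping members (`tally = "variants"`). Each permutation
#' draws, for every AVS, a size-matched set of background variants (one
#' global without-replacement draw per permutation, split across AVS) and
#' recomputes the tally. The p-value is the proportion of permutations with
#' null tally >= observed; `smooth = TRUE` uses (hits + 1) / (n + 1).
#'
#' @param avs data.frame from [build_avs()].
#' @param peaks interval track (e.g. ChIP-seq peaks of one mark).
#' @param background data.frame (id, chrom, pos) of background variants;
#'   should be disjoint from the AVS variants and at least as large as the
#'   total AVS size.
#' @param n_perm number of permutations (default 50000).
#' @param seed integer RNG seed; fixed seed gives bit-identical null
#'   tallies.
#' @param tally "loci" or "variants".
#' @param smooth add-one smoothing of the empirical p (default FALSE).
#' @return list of class "enrichment_result": observed_tally, null_tallies,
#'   n_perm, p_value.
#' @export
avs_enrichment <- function(avs, peaks, background, n_perm = 50000L, seed = 1L,
                           tally = c("loci", "variants"), smooth = FALSE) {
  tally <- match.arg(tally)
  sizes <- table(avs$locus_id)
  total <- sum(sizes)
  if (nrow(background) < max(sizes))
    stop("background pool (", nrow(background),
         ") smaller than the largest AVS (",
         names(sizes)[which.max(sizes)], ", size ", max(sizes), ")",
         call. = FALSE)
  if (nrow(background) < total)
    stop("background pool smaller than the total AVS size (", total, ")",
         call. = FALSE)
  in_peak_avs <- points_in_any_interval(avs$chrom, avs$pos, peaks)
  grp <- match(avs$locus_id, names(sizes))
  observed <- if (tally == "loci") {
    sum(rowsum(as.numeric(in_peak_avs), grp) > 0)
  } else sum(in_peak_avs)
  flags <- points_in_any_interval(background$chrom, background$pos, peaks)
  null_grp <- rep(seq_along(sizes), as.vector(sizes))
  set.seed(seed)
  nulls <- integer(n_perm)
  m <- length(flags)
  for (b in seq_len(n_perm)) {
    f <- flags[sample.int(m, total)]
    nulls[b] <- if (tally == "loci") sum(rowsum(as.numeric(f), null_grp) > 0)
    else sum(f)
  }
  structure(list(observed_tally = as.integer(observed), null_tallies = nulls,
                 n_perm = as.integer(n_perm),
                 p_value = .empirical_p(observed, nulls, smooth)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation enrichment: observed tally", x$observed_tally,
      "| permutations", x$n_perm, "| p =", format(x$p_value), "\n")
  invisible(x)
}

#' Transcription-factor count permutation enrichment
#'
#' The observed statistic counts bound TF sites overlapping the GWAS
#' regions. Each permutation centres windows of the same sizes as the
#' observed regions on variants drawn from the null pool (association
#' P > 0.95) and recounts. If the pool is smaller than the number of
#' regions, sampling falls back to with-replacement with a warning.
#'
#' @param gwas_regions interval track of the observed regions.
#' @param tf_sites data.frame (chrom, start, end, tf, bound) of predicted
#'   TF binding sites; only `bound == 1` rows are counted.
#' @param null_pool data.frame (id, chrom, pos) of null variants.
#' @param n_perm number of permutations (default 50000).
#' @param seed integer RNG seed.
#' @param smooth add-one smoothing of the empirical p (default FALSE).
#' @return list of class "enrichment_result".
#' @export
tf_count_enrichment <- function(gwas_regions, tf_sites, null_pool,
                                n_perm = 50000L, seed = 1L, smooth = FALSE) {
  bound <- tf_sites[tf_sites$bound %in% c(1, TRUE), , drop = FALSE]
  count_in <- function(chrom, start, end) {
    tot <- 0L
    for (ch in unique(chrom)) {
      bs <- bound[bound$chrom == ch, , drop = FALSE]
      if (!nrow(bs)) next
      sel <- which(chrom == ch)
      for (i in sel)
        tot <- tot + sum(bs$start < end[i] & start[i] < bs$end)
    }
    tot
  }
  observed <- count_in(gwas_regions$chrom, gwas_regions$start,
                       gwas_regions$end)
  widths <- gwas_regions$end - gwas_regions$start
  nreg <- nrow(gwas_regions)
  replace <- nrow(null_pool) < nreg
  if (replace)
    warning("null pool smaller than the number of regions; sampling with replacement",
            call. = FALSE)
  set.seed(seed)
  nulls <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(nrow(null_pool), nreg, replace = replace)
    ctr <- null_pool$pos[idx] - 1
    nulls[b] <- count_in(null_pool$chrom[idx],
                         pmax(0, ctr - floor(widths / 2)),
                         ctr + ceiling(widths / 2))
  }
  structure(list(observed_tally = as.integer(observed), null_tallies = nulls,
                 n_perm = as.integer(n_perm),
                 p_value = .empirical_p(observed, nulls, smooth)),
            class = "enrichment_result")
}
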