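#' vartier: integrative scoring and tiering of GWAS risk variants
#'
#' Coordinate conventions used throughout: interval tracks (BED-style) are
#' 0-based half-open `[start, end)`; variant and TSS positions are 1-based
#' points. The bridge between the two is exactly `pos - 1 \%in\% [start, end)`
#' (see [variant_in_interval()]). Chromosome names are compared verbatim;
#' no "chr" normalization is ever applied.
#'
#' @keywords internal
"_PACKAGE"

# ---- domain-table constructors ----------------------------------------------

#' Build a validated variant table
#'
#' A variant is a 1-based genomic point with alleles, a GWAS association
#' P value and (optionally) LD summaries relative to its locus lead.
#'
#' @param id character variant identifiers (unique).
#' @param chrom chromosome names (verbatim, no normalization).
#' @param pos 1-based positions (integer, >= 1).
#' @param ref,alt alleles.
#' @param gwas_p association P values in (0, 1]; NA allowed.
#' @param locus_id optional locus labels.
#' @param is_lead logical lead-variant flags.
#' @param r2_to_lead,dprime_to_lead LD to the locus lead, in [0, 1]; NA when
#'   unknown.
#' @return data.frame with one row per variant.
#' @export
variant_table <- function(id, chrom, pos, ref = NA_character_,
                          alt = NA_character_, gwas_p = NA_real_,
                          locus_id = NA_character_, is_lead = FALSE,
                          r2_to_lead = NA_real_, dprime_to_lead = NA_real_) {
  pos <- as.integer(pos)
  if (anyNA(pos) || any(pos < 1L))
    stop("variant positions must be integers >= 1", call. = FALSE)
  if (anyDuplicated(id))
    stop("variant ids must be unique", call. = FALSE)
  p <- as.numeric(gwas_p)
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad))
    stop("gwas_p must lie in (0, 1]; offending ids: ",
         paste(utils::head(id[bad], 5), collapse = ", "), call. = FALSE)
  for (nm in c("r2_to_lead", "dprime_to_lead")) {
    v <- as.numeric(get(nm))
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  data.frame(id = as.character(id), chrom = as.character(chrom), pos = pos,
             ref = as.character(ref), alt = as.character(alt), gwas_p = p,
             locus_id = as.character(locus_id),
             is_lead = as.logical(is_lead),
             r2_to_lead = as.numeric(r2_to_lead),
             dprime_to_lead = as.numeric(dprime_to_lead),
             stringsAsFactors = FALSE)
}

#' Build a validated interval track (0-based half-open)
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param label optional labels (e.g. chromatin state, peak name).
#' @param score optional numeric scores.
#' @return data.frame sorted by (chrom, start), stable for equal keys.
#' @export
interval_track <- function(chrom, start, end, label = NULL, score = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyNA(start) || anyNA(end) || any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.character(label)
  if (!is.null(score)) df$score <- as.numeric(score)
  df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
}

#' Build a validated gene-model table
#'
#' Gene bodies are 0-based half-open intervals; the TSS is a 1-based point
#' that must fall inside the body (start end for `+`, end for `-` by the
#' usual convention, but any interior point is accepted).
#'
#' @param gene_id gene identifiers (unique).
#' @param chrom chromosome names.
#' @param start,end gene body, 0-based half-open.
#' @param tss_pos 1-based TSS positions.
#' @param strand "+" or "-".
#' @return data.frame with one row per gene.
#' @export
gene_models <- function(gene_id, chrom, start, end, tss_pos, strand) {
  start <- as.numeric(start); end <- as.numeric(end)
  tss_pos <- as.integer(tss_pos)
  if (any(start < 0) || any(start >= end))
    stop("gene bodies must satisfy 0 <= start < end", call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  inside <- (tss_pos - 1L) >= start & (tss_pos - 1L) < end
  if (!all(inside))
    stop("tss_pos must lie within the gene body: ",
         paste(utils::head(gene_id[!inside], 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique", call. = FALSE)
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             start = start, end = end, tss_pos = tss_pos,
             strand = as.character(strand), stringsAsFactors = FALSE)
}

# ---- readers / writers ------------------------------------------------------

#' Read lines of a tab-separated track file, skipping '#' metadata
#' @noRd
.read_track_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Load a BED-style interval track
#'
#' Supported dialects: `bed3` (chrom, start, end), `bed4_label` (+ label
#' column) and `bed5_score` (+ label + numeric score). Coordinates are
#' 0-based half-open. Malformed lines are reported with their line number.
#'
#' @param path file path.
#' @param dialect one of "bed3", "bed4_label", "bed5_score".
#' @return interval data.frame sorted by (chrom, start); empty files give a
#'   zero-row track.
#' @export
load_interval_track <- function(path,
                                dialect = c("bed3", "bed4_label", "bed5_score")) {
  dialect <- match.arg(dialect)
  need <- switch(dialect, bed3 = 3L, bed4_label = 4L, bed5_score = 5L)
  tl <- .read_track_lines(path)
  if (length(tl$lines) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
    if (need >= 4L) out$label <- character()
    if (need >= 5L) out$score <- numeric()
    return(out)
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld < need))
    stop(sprintf("format error: line %d of %s has %d column(s), %d required for dialect '%s'",
                 tl$lineno[which(nfld < need)[1]], path,
                 nfld[which(nfld < need)[1]], need, dialect), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop(sprintf("format error: non-numeric coordinates at line %d of %s",
                 tl$lineno[which(bad)[1]], path), call. = FALSE)
  inv <- start < 0 | start >= end
  if (any(inv))
    stop(sprintf("validation error: start >= end (or start < 0) at line %d of %s",
                 tl$lineno[which(inv)[1]], path), call. = FALSE)
  label <- if (need >= 4L) vapply(fields, `[[`, "", 4L) else NULL
  score <- NULL
  if (need >= 5L) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (anyNA(score))
      stop(sprintf("format error: non-numeric score at line %d of %s",
                   tl$lineno[which(is.na(score))[1]], path), call. = FALSE)
  }
  interval_track(chrom, start, end, label = label, score = score)
}

#' Write a BED-style interval track
#'
#' The dialect is inferred from the columns present (`label`, `score`).
#' `meta` lines are written as '#'-prefixed headers and ignored on read, so
#' write-then-read round-trips coordinates and labels exactly.
#'
#' @param track interval data.frame (see [interval_track()]).
#' @param path output path.
#' @param meta optional character vector of metadata lines (without '#').
#' @return `path`, invisibly.
#' @export
write_interval_track <- function(track, path, meta = character()) {
  cols <- c("chrom", "start", "end",
            intersect(c("label", "score"), names(track)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  if (nrow(track)) {
    body <- do.call(paste, c(unname(lapply(cols, function(cn)
      .fmt_col(track[[cn]]))), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Load a BEDPE-like chromatin-interaction track
#'
#' Expects seven tab-separated columns: chromA, startA, endA, chromB,
#' startB, endB, -log10(P). Records with a negative significance column are
#' rejected; anchor coordinates are validated like intervals. Input order is
#' preserved.
#'
#' @param path file path.
#' @return data.frame with columns chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b, neg_log10_p.
#' @export
load_interaction_track <- function(path) {
  tl <- .read_track_lines(path)
  empty <- data.frame(chrom_a = character(), start_a = numeric(),
                      end_a = numeric(), chrom_b = character(),
                      start_b = numeric(), end_b = numeric(),
                      neg_log10_p = numeric(), stringsAsFactors = FALSE)
  if (length(tl$lines) == 0L) return(empty)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld != 7L))
    stop(sprintf("format error: line %d of %s has %d column(s), 7 required",
                 tl$lineno[which(nfld != 7L)[1]], path,
                 nfld[which(nfld != 7L)[1]]), call. = FALSE)
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  out <- data.frame(chrom_a = vapply(fields, `[[`, "", 1L),
                    start_a = num(2L), end_a = num(3L),
                    chrom_b = vapply(fields, `[[`, "", 4L),
                    start_b = num(5L), end_b = num(6L),
                    neg_log10_p = num(7L), stringsAsFactors = FALSE)
  if (anyNA(out$start_a) || anyNA(out$end_a) || anyNA(out$start_b) ||
      anyNA(out$end_b) || anyNA(out$neg_log10_p))
    stop("format error: non-numeric field in ", path, call. = FALSE)
  bad <- out$start_a < 0 | out$start_a >= out$end_a |
    out$start_b < 0 | out$start_b >= out$end_b
  if (any(bad))
    stop(sprintf("validation error: invalid anchor coordinates at line %d of %s",
                 tl$lineno[which(bad)[1]], path), call. = FALSE)
  if (any(out$neg_log10_p < 0))
    stop(sprintf("validation error: negative -log10(P) at line %d of %s",
                 tl$lineno[which(out$neg_log10_p < 0)[1]], path), call. = FALSE)
  out
}

#' Write a BEDPE-like interaction track
#' @param interactions data.frame as returned by [load_interaction_track()].
#' @param path output path.
#' @param meta optional '#' metadata lines.
#' @return `path`, invisibly.
#' @export
write_interaction_track <- function(interactions, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  if (nrow(interactions)) {
    cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
              "neg_log10_p")
    body <- do.call(paste, c(unname(lapply(cols, function(cn)
      .fmt_col(interactions[[cn]]))), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

# ---- coordinate bridge ------------------------------------------------------

#' Is a 1-based point inside a 0-based half-open interval?
#'
#' The single coordinate-convention bridge of the package:
#' `pos` is inside `[start, end)` iff `start <= pos - 1 < end`.
#' All arguments recycle.
#'
#' @param pos 1-based point position(s).
#' @param start,end 0-based half-open interval(s).
#' @return logical vector.
#' @export
variant_in_interval <- function(pos, start, end) {
  (pos - 1) >= start & (pos - 1) < end
}

#' Format a column for tab-separated output without padding
#' @noRd
.fmt_col <- function(x) {
  if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE)
  else as.character(x)
}

#' Which points fall inside any interval of a track?
#'
#' Handles overlapping intervals via a sorted cumulative-max sweep; verbatim
#' chromosome matching.
#'
#' @param chrom,pos point chromosomes and 1-based positions (recycled to a
#'   common length).
#' @param track interval data.frame.
#' @return logical vector, one per point.
#' @export
points_in_any_interval <- function(chrom, pos, track) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  hit <- logical(n)
  if (!nrow(track)) return(hit)
  p0 <- pos - 1
  for (ch in unique(chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!nrow(tr)) next
    o <- order(tr$start, method = "radix")
    s <- tr$start[o]
    emax <- cummax(tr$end[o])
    idx <- findInterval(p0[sel], s)
    ok <- idx > 0L
    ok[ok] <- emax[idx[ok]] > p0[sel][ok]
    hit[sel] <- ok
  }
  hit
}

#' Label of the segment containing each point
#'
#' For (near-)non-overlapping segmentations such as chromatin-state tracks.
#' Points not covered by any segment get NA.
#'
#' @param chrom,pos point chromosomes and 1-based positions.
#' @param segmentation interval data.frame with a `label` column.
#' @return character vector of labels (NA when uncovered).
#' @export
segment_label_at <- function(chrom, pos, segmentation) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- rep(NA_character_, n)
  if (!nrow(segmentation)) return(out)
  p0 <- pos - 1
  for (ch in unique(chrom)) {
    tr <- segmentation[segmentation$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!nrow(tr)) next
    o <- order(tr$start, method = "radix")
    s <- tr$start[o]; e <- tr$end[o]; lab <- tr$label[o]
    idx <- findInterval(p0[sel], s)
    ok <- idx > 0L
    ok[ok] <- e[idx[ok]] > p0[sel][ok]
    val <- rep(NA_character_, sum(sel))
    val[ok] <- lab[idx[ok]]
    out[sel] <- val
  }
  out
}

# ---- generic TSV with '#' metadata ------------------------------------------

#' Write a table as TSV with '#'-prefixed metadata lines
#' @param df data.frame.
#' @param path output path.
#' @param meta character vector of metadata lines (without '#').
#' @return `path`, invisibly.
#' @export
write_meta_tsv <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_meta_tsv()]
#' @param path file path.
#' @return data.frame (metadata lines skipped).
#' @export
read_meta_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}
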