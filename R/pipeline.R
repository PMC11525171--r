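# End-to-end orchestration: raw input directory -> locus, score, consensus,
# tier, gene-link and report tables, all written as auditable TSV
# intermediates with '#' metadata headers.

#' Read a simulated / user-provided input bundle
#'
#' Expects the file layout written by [simulate_dataset()]: `gwas.tsv`,
#' `ld.tsv`, `finemap.tsv`, `mpra.tsv`, `smr.tsv`, `akita.tsv`,
#' `genes.tsv`, `tf_sites.tsv`, and per-cell-line `atac_*.bed`,
#' `ctcf_*.bed`, `chromhmm_*.bed`, `abc_*.tsv`, `tfscore_*.tsv`,
#' `microc_*.bedpe`.
#'
#' @param dir input directory.
#' @return named list of tables and per-cell-line track lists.
#' @export
read_input_bundle <- function(dir) {
  req <- c("gwas.tsv", "ld.tsv", "finemap.tsv", "mpra.tsv", "smr.tsv",
           "akita.tsv", "genes.tsv")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing))
    stop("input bundle at ", dir, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  per_line <- function(prefix, ext, reader, dialect = NULL) {
    files <- sort(list.files(dir, pattern = paste0("^", prefix, "_.*\\.",
                                                   ext, "$"),
                             full.names = TRUE))
    cls <- sub(paste0("\\.", ext, "$"), "",
               sub(paste0("^", prefix, "_"), "", basename(files)))
    out <- lapply(files, function(f)
      if (is.null(dialect)) reader(f) else reader(f, dialect))
    stats::setNames(out, cls)
  }
  gwas <- read_meta_tsv(file.path(dir, "gwas.tsv"))
  list(
    variants = variant_table(gwas$id, gwas$chrom, gwas$pos, gwas$ref,
                             gwas$alt, gwas$p),
    ld = read_meta_tsv(file.path(dir, "ld.tsv")),
    finemap = read_meta_tsv(file.path(dir, "finemap.tsv")),
    mpra = read_meta_tsv(file.path(dir, "mpra.tsv")),
    smr = read_meta_tsv(file.path(dir, "smr.tsv")),
    akita = read_meta_tsv(file.path(dir, "akita.tsv")),
    genes = {
      g <- read_meta_tsv(file.path(dir, "genes.tsv"))
      gene_models(g$gene_id, g$chrom, g$start, g$end, g$tss_pos, g$strand)
    },
    tf_sites = if (file.exists(file.path(dir, "tf_sites.tsv")))
      read_meta_tsv(file.path(dir, "tf_sites.tsv")) else NULL,
    atac = per_line("atac", "bed", load_interval_track, "bed3"),
    ctcf = per_line("ctcf", "bed", load_interval_track, "bed3"),
    chromhmm = per_line("chromhmm", "bed", load_interval_track,
                        "bed4_label"),
    microc = per_line("microc", "bedpe", load_interaction_track),
    abc = per_line("abc", "tsv", read_meta_tsv),
    tfscore = per_line("tfscore", "tsv", read_meta_tsv))
}

#' Run the whole prioritization pipeline
#'
#' define loci -> select candidate variants -> credible sets -> all
#' annotation scores -> cross-cell-line consensus -> tier assignment ->
#' effector-gene nomination -> summary report. Every stage's table is
#' written to `out_dir` as TSV with '#' metadata (version, thresholds,
#' seed). The pipeline itself is deterministic: re-running on the same
#' inputs gives byte-identical outputs.
#'
#' @param input_dir directory with the input bundle (see
#'   [read_input_bundle()]).
#' @param out_dir output directory (created if absent).
#' @param cfg [scoring_config()].
#' @param p_threshold,min_separation_bp,window_bp locus-definition
#'   parameters (see [define_loci()]).
#' @param coverage,min_pip credible-set parameters (see
#'   [build_credible_set()]).
#' @param per_locus_tiers if TRUE, tiers are assigned within each locus
#'   instead of globally (comparison mode; the default, FALSE, ranks all
#'   scored variants together).
#' @return invisibly, a list with every stage table: loci, candidates,
#'   credible_sets, term_scores, consensus, totals, tiers, gene_links,
#'   report.
#' @export
run_pipeline <- function(input_dir, out_dir = file.path(input_dir, "out"),
                         cfg = scoring_config(), p_threshold = 5e-8,
                         min_separation_bp = 500000L, window_bp = 250000L,
                         coverage = 0.95, min_pip = 0.001,
                         per_locus_tiers = FALSE) {
  inp <- read_input_bundle(input_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(paste("vartier", as.character(utils::packageVersion("vartier"))),
            paste("p_threshold:", p_threshold),
            paste("min_separation_bp:", min_separation_bp),
            paste("window_bp:", window_bp),
            paste("coverage:", coverage), paste("min_pip:", min_pip),
            paste("mpra_fdr_strong:", cfg$mpra_fdr_strong),
            paste("mpra_fdr_hit:", cfg$mpra_fdr_hit),
            paste("pip_strong:", cfg$pip_strong),
            paste("akita_window_bp:", cfg$akita_window_bp),
            paste("akita_frac:", cfg$akita_frac),
            paste("microc_min_neg_log10_p:", cfg$microc_min_neg_log10_p),
            paste("consensus_p0:", cfg$consensus_p0),
            paste("tiering:", if (per_locus_tiers) "per-locus" else "global"))

  # --- stage 1: loci and candidate variants
  loci <- define_loci(inp$variants, p_threshold, min_separation_bp, window_bp)
  if (!nrow(loci))
    stop("stage define-loci: no variant reaches the significance threshold",
         call. = FALSE)
  members <- locus_members(inp$variants, loci)
  cand_list <- lapply(seq_len(nrow(loci)), function(i) {
    mem_ids <- members$variant_id[members$locus_id == loci$locus_id[i]]
    mv <- inp$variants[inp$variants$id %in% mem_ids, , drop = FALSE]
    ld <- inp$ld[inp$ld$lead_id == loci$lead_id[i], , drop = FALSE]
    mv$r2_to_lead <- ld$r2[match(mv$id, ld$variant_id)]
    mv$dprime_to_lead <- ld$dprime[match(mv$id, ld$variant_id)]
    sel <- select_candidate_variants(mv, loci$lead_id[i])
    sel$locus_id <- loci$locus_id[i]
    sel$is_lead <- sel$id == loci$lead_id[i]
    sel
  })
  candidates <- do.call(rbind, c(cand_list, list(make.row.names = FALSE)))
  # a variant that falls in two overlapping windows is scored once but
  # kept as a member of both loci for gene nomination
  membership <- candidates[c("locus_id", "id")]
  names(membership) <- c("locus_id", "variant_id")
  scored <- candidates[!duplicated(candidates$id), , drop = FALSE]
  write_meta_tsv(loci, file.path(out_dir, "loci.tsv"), meta)
  write_meta_tsv(candidates, file.path(out_dir, "candidates.tsv"), meta)

  # --- stage 2: credible sets (per locus, over that locus's members)
  cs_list <- lapply(seq_len(nrow(loci)), function(i) {
    ids <- membership$variant_id[membership$locus_id == loci$locus_id[i]]
    fm <- inp$finemap[inp$finemap$variant_id %in% ids, , drop = FALSE]
    cs <- build_credible_set(fm, coverage, min_pip)
    if (length(cs)) data.frame(locus_id = loci$locus_id[i], variant_id = cs,
                               stringsAsFactors = FALSE)
  })
  cs_list <- Filter(Negate(is.null), cs_list)
  credible <- if (length(cs_list)) {
    do.call(rbind, c(cs_list, list(make.row.names = FALSE)))
  } else {
    data.frame(locus_id = character(), variant_id = character(),
               stringsAsFactors = FALSE)
  }
  write_meta_tsv(credible, file.path(out_dir, "credible_sets.tsv"), meta)

  # --- stage 3: per-term scores
  vt <- scored
  pip <- inp$finemap$pip[match(vt$id, inp$finemap$variant_id)]
  term_rows <- list(
    data.frame(variant_id = vt$id, term = "FINEMAP", cell_line = NA,
               value = score_finemap(pip, vt$id %in% credible$variant_id,
                                     cfg), stringsAsFactors = FALSE),
    data.frame(variant_id = vt$id, term = "AKITA", cell_line = NA,
               value = score_akita(vt, inp$akita, cfg),
               stringsAsFactors = FALSE))
  for (tissue in c("normal", "tumor")) {
    smr_t <- inp$smr[inp$smr$tissue == tissue, , drop = FALSE]
    smr_t$locus_id <- membership$locus_id[match(smr_t$variant_id,
                                                membership$variant_id)]
    smr_t <- smr_t[!is.na(smr_t$locus_id), , drop = FALSE]
    gpl <- genes_per_locus(inp$genes, loci)
    passing <- filter_smr(smr_t, gpl)
    term_rows[[length(term_rows) + 1L]] <- data.frame(
      variant_id = vt$id, term = paste0("SMR_", toupper(tissue)),
      cell_line = NA, value = score_smr(vt$id, passing),
      stringsAsFactors = FALSE)
    if (tissue == "normal") smr_normal_pass <- passing
    else smr_tumor_pass <- passing
  }
  mp <- inp$mpra[inp$mpra$variant_id %in% vt$id, , drop = FALSE]
  term_rows[[length(term_rows) + 1L]] <- data.frame(
    variant_id = mp$variant_id, term = paste0("MPRA_", mp$cell_line),
    cell_line = mp$cell_line, value = score_mpra(mp$fdr, cfg),
    stringsAsFactors = FALSE)
  per_line_scores <- function(tracks, term, scorer) {
    rows <- lapply(names(tracks), function(cl)
      data.frame(variant_id = vt$id, term = term, cell_line = cl,
                 value = scorer(tracks[[cl]]), stringsAsFactors = FALSE))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  cell_rows <- rbind(
    per_line_scores(inp$atac, "ATAC",
                    function(tr) score_peak_overlap(vt, tr)),
    per_line_scores(inp$ctcf, "CTCF",
                    function(tr) score_peak_overlap(vt, tr)),
    per_line_scores(inp$chromhmm, "CHROMHMM",
                    function(tr) score_chromhmm(vt, tr, cfg)),
    per_line_scores(inp$microc, "MICROC",
                    function(tr) score_microc(vt, tr, inp$genes, cfg)))

  # --- stage 4: consensus
  cons_list <- list()
  for (term in c("ATAC", "CTCF", "CHROMHMM", "MICROC")) {
    sub <- cell_rows[cell_rows$term == term, , drop = FALSE]
    for (v in vt$id) {
      mc <- majority_consensus(sub$value[sub$variant_id == v])
      cons_list[[length(cons_list) + 1L]] <- data.frame(
        variant_id = v, term = term, value = mc$value,
        n_cell_lines = mc$n_cell_lines, n_supporting = mc$n_supporting,
        stringsAsFactors = FALSE)
    }
  }
  flags_consensus <- function(tables, term, score_col) {
    full <- lapply(tables, function(tb)
      data.frame(item_id = tb$variant_id, score = tb[[score_col]],
                 stringsAsFactors = FALSE))
    # flags use each cell line's full score distribution as reference
    fl <- percentile_hit_flags(full)
    fl <- fl[fl$item_id %in% vt$id, , drop = FALSE]
    kk <- tapply(fl$flag, fl$item_id, sum)
    nn <- tapply(rep(1L, nrow(fl)), fl$item_id, sum)
    val <- binomial_consensus(as.integer(kk), as.integer(nn),
                              p0 = cfg$consensus_p0)
    out <- data.frame(variant_id = vt$id, term = term, value = 0L,
                      n_cell_lines = 0L, n_supporting = 0L,
                      stringsAsFactors = FALSE)
    m <- match(names(kk), out$variant_id)
    out$value[m] <- val
    out$n_cell_lines[m] <- as.integer(nn)
    out$n_supporting[m] <- as.integer(kk)
    out
  }
  cons <- rbind(do.call(rbind, c(cons_list, list(make.row.names = FALSE))),
                flags_consensus(inp$abc, "ABC", "abc_score"),
                flags_consensus(inp$tfscore, "TF", "score"))
  write_meta_tsv(cons, file.path(out_dir, "consensus.tsv"), meta)

  # --- stage 5: totals and tiers
  term_scores <- rbind(
    do.call(rbind, c(term_rows,
                     list(make.row.names = FALSE)))[c("variant_id", "term",
                                                      "value")],
    cons[c("variant_id", "term", "value")])
  write_meta_tsv(term_scores, file.path(out_dir, "scores.tsv"), meta)
  totals <- sum_scores(term_scores)
  # variants with no score row at all (none here, but defensive) get 0
  if (per_locus_tiers) {
    tiers <- do.call(rbind, lapply(split(membership, membership$locus_id),
                                   function(mm) {
      tt <- totals[totals$variant_id %in% mm$variant_id, , drop = FALSE]
      cbind(locus_id = mm$locus_id[1], assign_tiers(tt))
    }))
    row.names(tiers) <- NULL
  } else {
    tiers <- assign_tiers(totals)
  }
  write_meta_tsv(tiers, file.path(out_dir, "tiers.tsv"), meta)

  # --- stage 6: gene evidence and nomination
  evidence <- rbind(
    if (nrow(smr_normal_pass))
      data.frame(variant_id = smr_normal_pass$variant_id,
                 gene_id = smr_normal_pass$gene_id, source = "SMR_NORMAL",
                 stringsAsFactors = FALSE),
    if (nrow(smr_tumor_pass))
      data.frame(variant_id = smr_tumor_pass$variant_id,
                 gene_id = smr_tumor_pass$gene_id, source = "SMR_TUMOR",
                 stringsAsFactors = FALSE),
    abc_gene_evidence(inp$abc, vt$id, cfg),
    microc_tss_evidence(inp$microc, vt, inp$genes, cfg, contact = "tss"))
  microc_body <- microc_tss_evidence(inp$microc, vt, inp$genes, cfg,
                                     contact = "body")[c("variant_id",
                                                         "gene_id")]
  tier_for_link <- if (per_locus_tiers) {
    tiers[!duplicated(tiers$variant_id), c("variant_id", "tier")]
  } else tiers[c("variant_id", "tier")]
  links <- nominate_genes(tier_for_link, membership, evidence, microc_body,
                          vt, inp$genes)
  write_meta_tsv(links, file.path(out_dir, "gene_links.tsv"), meta)

  # --- stage 7: report
  report <- report_summary(tiers, links, membership, vt, inp$genes)
  write_meta_tsv(report$per_locus, file.path(out_dir, "report_loci.tsv"),
                 meta)
  writeLines(report$text, file.path(out_dir, "report.txt"))

  invisible(list(loci = loci, candidates = candidates,
                 credible_sets = credible, term_scores = term_scores,
                 consensus = cons, totals = totals, tiers = tiers,
                 evidence = evidence, gene_links = links, report = report))
}

#' Count genes whose TSS lies inside each locus window
#' @param genes gene-model data.frame.
#' @param loci locus table from [define_loci()].
#' @return named integer vector locus_id -> gene count (min 1, so the SMR
#'   Bonferroni correction is always defined).
#' @export
genes_per_locus <- function(genes, loci) {
  out <- vapply(seq_len(nrow(loci)), function(i)
    sum(genes$chrom == loci$chrom[i] &
          variant_in_interval(genes$tss_pos, loci$window_start[i],
                              loci$window_end[i])), integer(1))
  stats::setNames(pmax(out, 1L), loci$locus_id)
}

#' ABC (variant, gene) evidence pairs
#'
#' A pair is evidence when its per-cell-line 90th-percentile flags reach a
#' binomial-consensus score of at least 1.
#'
#' @param abc_tables named list (cell line -> data.frame(variant_id,
#'   gene_id, abc_score)).
#' @param variant_ids candidate variant ids.
#' @param cfg [scoring_config()].
#' @return data.frame (variant_id, gene_id, source = "ABC").
#' @export
abc_gene_evidence <- function(abc_tables, variant_ids,
                              cfg = scoring_config()) {
  empty <- data.frame(variant_id = character(), gene_id = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (!length(abc_tables)) return(empty)
  pair_tabs <- lapply(abc_tables, function(tb)
    data.frame(item_id = paste(tb$variant_id, tb$gene_id, sep = "\r"),
               score = tb$abc_score, stringsAsFactors = FALSE))
  fl <- percentile_hit_flags(pair_tabs)
  if (!nrow(fl)) return(empty)
  kk <- tapply(fl$flag, fl$item_id, sum)
  nn <- tapply(rep(1L, nrow(fl)), fl$item_id, sum)
  val <- binomial_consensus(as.integer(kk), as.integer(nn),
                            p0 = cfg$consensus_p0)
  keep <- names(kk)[val >= 1L]
  if (!length(keep)) return(empty)
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(variant_id = vapply(parts, `[[`, "", 1L),
                    gene_id = vapply(parts, `[[`, "", 2L), source = "ABC",
                    stringsAsFactors = FALSE)
  out[out$variant_id %in% variant_ids, , drop = FALSE]
}

#' Chromatin-contact gene evidence with cell-line majority
#'
#' (variant, gene) pairs whose TSS (or gene-body) contact is present in
#' strictly more than half of the chromatin-contact cell lines.
#'
#' @param microc_tracks named list (cell line -> interaction data.frame).
#' @param variants candidate variant data.frame (id, chrom, pos).
#' @param genes gene-model data.frame.
#' @param cfg [scoring_config()].
#' @param contact "tss" or "body".
#' @return data.frame (variant_id, gene_id, source).
#' @export
microc_tss_evidence <- function(microc_tracks, variants, genes,
                                cfg = scoring_config(),
                                contact = c("tss", "body")) {
  contact <- match.arg(contact)
  src <- if (contact == "tss") "MICROC_TSS" else "MICROC_BODY"
  empty <- data.frame(variant_id = character(), gene_id = character(),
                      source = character(), stringsAsFactors = FALSE)
  n_lines <- length(microc_tracks)
  if (!n_lines) return(empty)
  per_line <- lapply(microc_tracks, function(tr) {
    cc <- microc_gene_contacts(variants, tr, genes, cfg)
    cc[cc$contact == contact, c("variant_id", "gene_id"), drop = FALSE]
  })
  all_pairs <- do.call(rbind, c(per_line, list(make.row.names = FALSE)))
  if (!nrow(all_pairs)) return(empty)
  key <- paste(all_pairs$variant_id, all_pairs$gene_id, sep = "\r")
  cnt <- table(key)
  keep <- names(cnt)[cnt > n_lines / 2]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  data.frame(variant_id = vapply(parts, `[[`, "", 1L),
             gene_id = vapply(parts, `[[`, "", 2L), source = src,
             stringsAsFactors = FALSE)
}

#' Integer-rounded percentage
#' @param n numerator count.
#' @param total denominator count.
#' @return `round(100 * n / total)` as integer.
#' @export
pct_int <- function(n, total) as.integer(round(100 * n / total))

#' Summarize a pipeline run
#'
#' Per-locus tier counts, loci lacking Tier 1 (and Tier 1+2) variants,
#' link status per locus, and the fraction of nominated variants whose
#' target gene is also the closest gene (by TSS distance).
#'
#' @param tiers tier table from [assign_tiers()].
#' @param links gene-link table from [nominate_genes()].
#' @param membership data.frame (locus_id, variant_id).
#' @param variants candidate variant data.frame (id, chrom, pos).
#' @param genes gene-model data.frame.
#' @return list with `per_locus` (data.frame), `counts` (named list) and
#'   `text` (character lines).
#' @export
report_summary <- function(tiers, links, membership, variants, genes) {
  tier_of <- tiers[!duplicated(tiers$variant_id), ]
  tier_of <- stats::setNames(tier_of$tier, tier_of$variant_id)
  loci <- sort(unique(membership$locus_id))
  per_locus <- do.call(rbind, lapply(loci, function(l) {
    vs <- membership$variant_id[membership$locus_id == l]
    tt <- tier_of[vs]
    lk <- links[links$locus_id == l, , drop = FALSE]
    data.frame(locus_id = l, n_variants = length(vs),
               n_tier1 = sum(tt == 1L), n_tier2 = sum(tt == 2L),
               n_tier3 = sum(tt == 3L),
               n_strong_links = sum(lk$status == "strong"),
               n_weak_links = sum(lk$status == "weak"),
               stringsAsFactors = FALSE)
  }))
  row.names(per_locus) <- NULL
  closest_frac <- NA_real_
  nom <- links[links$status == "strong", , drop = FALSE]
  if (nrow(nom) && nrow(genes)) {
    hit <- vapply(seq_len(nrow(nom)), function(i) {
      vids <- strsplit(nom$variant_id[i], ",", fixed = TRUE)[[1]]
      vv <- variants[variants$id %in% vids, , drop = FALSE]
      any(vapply(seq_len(nrow(vv)), function(j) {
        g <- genes[genes$chrom == vv$chrom[j], , drop = FALSE]
        if (!nrow(g)) return(FALSE)
        g$gene_id[which.min(abs(g$tss_pos - vv$pos[j]))] == nom$gene_id[i]
      }, logical(1)))
    }, logical(1))
    closest_frac <- mean(hit)
  }
  counts <- list(
    n_variants = length(tier_of),
    n_tier = as.list(table(factor(tier_of, levels = 1:3))),
    n_loci = length(loci),
    loci_no_tier1 = per_locus$locus_id[per_locus$n_tier1 == 0L],
    loci_no_tier12 = per_locus$locus_id[per_locus$n_tier1 == 0L &
                                          per_locus$n_tier2 == 0L],
    loci_strong = sum(per_locus$n_strong_links > 0L),
    loci_weak_only = sum(per_locus$n_strong_links == 0L &
                           per_locus$n_weak_links > 0L),
    loci_no_link = sum(per_locus$n_strong_links + per_locus$n_weak_links ==
                         0L),
    closest_gene_frac = closest_frac)
  nt <- table(factor(tier_of, levels = 1:3))
  text <- c(
    sprintf("scored variants: %d", counts$n_variants),
    sprintf("tier counts: Tier1=%d (%d%%), Tier2=%d (%d%%), Tier3=%d (%d%%)",
            nt[1], pct_int(nt[1], counts$n_variants),
            nt[2], pct_int(nt[2], counts$n_variants),
            nt[3], pct_int(nt[3], counts$n_variants)),
    sprintf("loci: %d; without Tier 1 variants: %d; without Tier 1+2: %d",
            counts$n_loci, length(counts$loci_no_tier1),
            length(counts$loci_no_tier12)),
    sprintf("loci with strong links: %d; weak-only: %d; no link: %d",
            counts$loci_strong, counts$loci_weak_only, counts$loci_no_link),
    sprintf("strong-link genes that are the closest gene: %s",
            ifelse(is.na(closest_frac), "NA",
                   sprintf("%.0f%%", 100 * closest_frac))))
  list(per_locus = per_locus, counts = counts, text = text)
}
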