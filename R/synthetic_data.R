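# Synthetic-data generator: emits every input the pipeline consumes, as
# real files in the declared formats, plus a ground-truth manifest of
# planted causal variants and their target genes.
#
# The stated world: ~10 loci of ~40 candidate variants each (the study
# tested a median of 39 variants per locus), six chromatin cell lines,
# five chromatin-contact lines, three MPRA lines, three genes per locus.
# One causal variant is planted per selected locus; each supporting
# annotation is planted independently with probability `signal_strength`
# for causal variants and `background_rate` for the rest, and a planted
# annotation is emitted consistently across the relevant cell-line panel.

#' Simulation configuration
#'
#' @param n_loci number of risk loci (default 10).
#' @param variants_per_locus candidate variants per locus incl. the lead
#'   (default 40).
#' @param n_genes_per_locus genes whose TSS falls in each locus window
#'   (default 3).
#' @param frac_causal fraction of variants that are causal (default
#'   1/variants_per_locus, i.e. one per locus; at most one causal is
#'   planted per locus).
#' @param signal_strength probability a causal variant receives each
#'   supporting annotation (default 0.9).
#' @param background_rate same for non-causal variants (default 0.05);
#'   must be below `signal_strength` for recovery tests to be meaningful.
#' @param ld_decay_bp distance scale of the r-squared decay (default
#'   25000).
#' @param n_null_variants extra non-significant variants (P > 0.95)
#'   forming the permutation null pool (default 200).
#' @param n_filler_scores filler rows per cell line in the ABC / TF score
#'   tables, so 90th-percentile flags have a realistic reference
#'   distribution (default 200).
#' @param chip_cell_lines,microc_cell_lines,mpra_cell_lines assay rosters.
#' @param seed integer seed; all draws derive from it.
#' @return list of class "sim_config".
#' @export
sim_config <- function(n_loci = 10L, variants_per_locus = 40L,
                       n_genes_per_locus = 3L,
                       frac_causal = 1 / variants_per_locus,
                       signal_strength = 0.9, background_rate = 0.05,
                       ld_decay_bp = 25000L, n_null_variants = 200L,
                       n_filler_scores = 200L,
                       chip_cell_lines = c("C32", "CL11", "HT29", "SW403",
                                           "SW480", "SW948"),
                       microc_cell_lines = c("CL11", "HT29", "SW403",
                                             "SW480", "SW948"),
                       mpra_cell_lines = c("HT29", "SW403", "HCEC1CT"),
                       seed = 1L) {
  if (n_loci < 1 || variants_per_locus < 2 || n_genes_per_locus < 1)
    stop("all counts must be >= 1 (and >= 2 variants per locus)",
         call. = FALSE)
  n_total <- n_loci * variants_per_locus
  n_causal <- round(frac_causal * n_total)
  if (n_causal > n_total)
    stop("infeasible config: more causal variants than variants",
         call. = FALSE)
  if (n_causal > n_loci)
    stop("infeasible config: the generator plants at most one causal variant per locus (",
         n_causal, " requested for ", n_loci, " loci)", call. = FALSE)
  if (signal_strength < 0 || signal_strength > 1 || background_rate < 0 ||
      background_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(n_loci = as.integer(n_loci),
                 variants_per_locus = as.integer(variants_per_locus),
                 n_genes_per_locus = as.integer(n_genes_per_locus),
                 frac_causal = frac_causal, n_causal = as.integer(n_causal),
                 signal_strength = signal_strength,
                 background_rate = background_rate,
                 ld_decay_bp = as.integer(ld_decay_bp),
                 n_null_variants = as.integer(n_null_variants),
                 n_filler_scores = as.integer(n_filler_scores),
                 chip_cell_lines = chip_cell_lines,
                 microc_cell_lines = microc_cell_lines,
                 mpra_cell_lines = mpra_cell_lines,
                 seed = as.integer(seed)), class = "sim_config")
}

# annotation terms a causal variant can be planted with
.plantable_terms <- c("MPRA", "FINEMAP", "CHROMHMM", "ATAC", "CTCF",
                      "MICROC", "SMR_NORMAL", "SMR_TUMOR", "AKITA", "ABC",
                      "TF")

# Fixed 21-position disruption-score pattern for every +/-100 bp window
# (grid step 10 bp). 16 low values plus five at exactly 0.9 keep every
# unplanted window deterministically below the >25% exceedance rule, for
# any global top-10%/top-20% threshold the planted highs induce. Planted
# windows overwrite the 8 central positions with a constant high value.
.akita_low_pattern <- function() {
  v <- rep(0.9, 21)
  v[-c(3, 7, 11, 15, 19)] <- seq(0.01, 0.30, length.out = 16)
  v
}
.akita_high_idx <- c(5, 7, 9, 10, 11, 12, 13, 17)
.akita_high_value <- 5

#' Generate a complete synthetic input bundle
#'
#' Writes every file the pipeline consumes into `dir` (GWAS summary
#' statistics, LD table, fine-mapping PIPs, per-cell-line ATAC/CTCF peaks,
#' chromatin-state segmentations and chromatin-contact tracks, MPRA and
#' SMR tables, a disruption-score track, ABC / TF score tables, TF binding
#' sites, gene models, and a truth manifest). All randomness derives from
#' `cfg$seed`; a fixed seed gives byte-identical files.
#'
#' @param cfg [sim_config()].
#' @param dir output directory (created if absent).
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   (data.frame: variant_id, locus, gene_id, planted terms) and `data`
#'   (the in-memory tables).
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = tempfile("simdata")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  nl <- cfg$n_loci; vpl <- cfg$variants_per_locus
  chrom <- "chr1"
  centers <- 5e5 + (seq_len(nl) - 1L) * 1e6

  # --- variant positions: lead at the centre, causal 1.2-2 kb away, the
  # rest on a 1.5 kb lattice with +/-200 bp jitter (min spacing > 1 kb so
  # planted peaks/segments/anchors never leak onto a neighbour)
  slots <- seq(-2e5, 2e5, by = 1500)
  slots <- slots[abs(slots) > 3000]
  gw <- list(); ld <- list(); truth <- list()
  causal_loci <- sort(sample.int(nl, cfg$n_causal))
  for (i in seq_len(nl)) {
    has_causal <- i %in% causal_loci
    n_other <- vpl - 1L - as.integer(has_causal)
    off <- sample(slots, n_other) + sample(seq(-200L, 200L), n_other,
                                           replace = TRUE)
    causal_off <- if (has_causal) sample(1200:2000, 1L) else integer()
    offs <- c(0L, causal_off, off)
    ids <- sprintf("rs%d_%02d", seq_along(offs), i)
    role <- c("lead", if (has_causal) "causal", rep("bg", n_other))
    pos <- as.integer(centers[i] + offs)
    logp_lead <- stats::runif(1, 9, 15)
    # background members sit 0.2-3.5 orders of magnitude above the lead's
    # P, so most (~85%) qualify for testing via the 3-OOM rule, matching a
    # median of a few dozen tested variants per locus
    logp <- c(logp_lead,
              if (has_causal) logp_lead - stats::runif(1, 0.3, 2.0),
              logp_lead - 0.2 - stats::runif(n_other, 0, 3.3))
    d <- abs(offs)
    r2 <- pmin(1, exp(-d / cfg$ld_decay_bp) * stats::runif(length(d), 0.7, 1))
    r2[1] <- 1
    dprime <- pmin(1, sqrt(r2) + stats::runif(length(d), 0, 0.05))
    alleles <- matrix(sample(c("A", "C", "G", "T"), 2L * length(offs),
                             replace = TRUE), ncol = 2)
    gw[[i]] <- data.frame(id = ids, chrom = chrom, pos = pos,
                          ref = alleles[, 1],
                          alt = ifelse(alleles[, 2] == alleles[, 1], "T",
                                       alleles[, 2]),
                          p = 10^(-logp), role = role, sim_locus = i,
                          stringsAsFactors = FALSE)
    ld[[i]] <- data.frame(lead_id = ids[1], variant_id = ids, r2 = r2,
                          dprime = dprime, stringsAsFactors = FALSE)
  }
  gwas <- do.call(rbind, gw)
  ldtab <- do.call(rbind, ld)

  # null pool: P > 0.95, scattered between loci
  if (cfg$n_null_variants > 0) {
    null_zone <- as.vector(outer(seq(2.55e5, 4.95e5, by = 37), centers, "+"))
    null <- data.frame(
      id = sprintf("null%04d", seq_len(cfg$n_null_variants)), chrom = chrom,
      pos = as.integer(sort(sample(null_zone, cfg$n_null_variants))),
      ref = "A", alt = "G",
      p = stats::runif(cfg$n_null_variants, 0.9501, 1), role = "null",
      sim_locus = NA_integer_, stringsAsFactors = FALSE)
    gwas <- rbind(gwas, null)
  }

  # --- genes: 3 per locus in the 205-245 kb ring around the centre, bodies
  # clear of the variant span
  gn <- list()
  for (i in seq_len(nl)) {
    side <- rep_len(c(1, -1), cfg$n_genes_per_locus)
    base <- 2.05e5 + (seq_len(cfg$n_genes_per_locus) - 1L) %/% 2L * 1.5e4
    gstart <- centers[i] + side * base
    strand <- rep_len(c("+", "-"), cfg$n_genes_per_locus)
    s0 <- pmin(gstart, gstart + side * 1e4)
    e0 <- pmax(gstart, gstart + side * 1e4)
    tss <- ifelse(strand == "+", s0 + 1, e0)
    gn[[i]] <- data.frame(gene_id = sprintf("GENE%02d_%d", i,
                                            seq_len(cfg$n_genes_per_locus)),
                          chrom = chrom, start = s0, end = e0, tss_pos = tss,
                          strand = strand, sim_locus = i,
                          stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gn)

  # --- plant annotations
  cand <- gwas[gwas$role != "null", , drop = FALSE]
  is_causal <- cand$role == "causal"
  rate <- ifelse(is_causal, cfg$signal_strength, cfg$background_rate)
  planted <- matrix(stats::runif(nrow(cand) * length(.plantable_terms)) <
                      rate, nrow = nrow(cand),
                    dimnames = list(cand$id, .plantable_terms))
  # gene-evidence terms only make sense with a target gene: background
  # variants planted with SMR/ABC/MICROC point at a random locus gene,
  # causal variants at their designated target
  target_gene <- rep(NA_character_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    lg <- genes$gene_id[genes$sim_locus == cand$sim_locus[i]]
    target_gene[i] <- if (is_causal[i]) lg[1] else sample(lg, 1L)
  }

  # --- MPRA table (all candidate variants x MPRA lines)
  mp <- list()
  for (cl in cfg$mpra_cell_lines) {
    strong <- planted[, "MPRA"]
    fdr <- ifelse(strong, stats::runif(nrow(cand), 1e-5, 1e-3),
                  stats::runif(nrow(cand), 0.0501, 1))
    lr <- ifelse(strong,
                 sample(c(-1, 1), nrow(cand), replace = TRUE) *
                   stats::runif(nrow(cand), 0.5, 2),
                 stats::runif(nrow(cand), -0.2, 0.2))
    mp[[cl]] <- data.frame(variant_id = cand$id, cell_line = cl,
                           log_ratio = lr, fdr = fdr,
                           stringsAsFactors = FALSE)
  }
  mpra <- do.call(rbind, c(mp, list(make.row.names = FALSE)))
  # orient the causal MPRA effect once per variant (consistent across lines)
  eff_sign <- stats::setNames(sample(c(-1, 1), nrow(cand), replace = TRUE),
                              cand$id)
  mpra$log_ratio <- abs(mpra$log_ratio) * eff_sign[mpra$variant_id]

  # --- fine-mapping PIPs: planted FINEMAP concentrates the mass on the
  # planted variant; everything else stays below the 0.001 floor
  pip <- stats::runif(nrow(cand), 0, 5e-4)
  pip[planted[, "FINEMAP"]] <- stats::runif(sum(planted[, "FINEMAP"]),
                                            0.75, 0.95)
  finemap <- data.frame(variant_id = cand$id, pip = pip,
                        stringsAsFactors = FALSE)

  # --- per-cell-line peak / state / contact tracks
  # filler intervals live in the dead zone 260-490 kb right of each locus
  # centre: clear of every variant span, gene ring and null-free windows
  filler_starts <- as.vector(outer(seq(2.6e5, 4.9e5, by = 5e4), centers, "+"))
  atac <- ctcf <- chmm <- stats::setNames(
    vector("list", length(cfg$chip_cell_lines)), cfg$chip_cell_lines)
  for (cl in cfg$chip_cell_lines) {
    p0 <- cand$pos - 1
    mk_peaks <- function(term) {
      sel <- planted[, term]
      fil <- sample(filler_starts, min(8L, length(filler_starts)))
      interval_track(chrom, c(p0[sel] - 150, fil), c(p0[sel] + 150, fil + 400))
    }
    atac[[cl]] <- mk_peaks("ATAC")
    ctcf[[cl]] <- mk_peaks("CTCF")
    enh <- sort(p0[planted[, "CHROMHMM"]])
    bounds <- sort(unique(c(0, nl * 1e6, enh - 200, enh + 200)))
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1]
    lab <- rep("Quies", length(seg_start))
    lab[seg_start %in% (enh - 200)] <- "Enh"
    chmm[[cl]] <- interval_track(chrom, seg_start, seg_end, label = lab)
  }

  microc <- stats::setNames(vector("list", length(cfg$microc_cell_lines)),
                            cfg$microc_cell_lines)
  mc_sel <- which(planted[, "MICROC"])
  for (cl in cfg$microc_cell_lines) {
    if (length(mc_sel)) {
      p0 <- cand$pos[mc_sel] - 1
      tss0 <- genes$tss_pos[match(target_gene[mc_sel], genes$gene_id)] - 1
      microc[[cl]] <- data.frame(
        chrom_a = chrom, start_a = p0 - 100, end_a = p0 + 100,
        chrom_b = chrom, start_b = tss0 - 500, end_b = tss0 + 500,
        neg_log10_p = stats::runif(length(mc_sel), 2, 6),
        stringsAsFactors = FALSE)
    } else {
      microc[[cl]] <- data.frame(chrom_a = character(), start_a = numeric(),
                                 end_a = numeric(), chrom_b = character(),
                                 start_b = numeric(), end_b = numeric(),
                                 neg_log10_p = numeric(),
                                 stringsAsFactors = FALSE)
    }
  }

  # --- SMR tables: planted rows pass both filters, fillers fail
  smr <- list()
  for (tissue in c("normal", "tumor")) {
    term <- if (tissue == "normal") "SMR_NORMAL" else "SMR_TUMOR"
    sel <- which(planted[, term])
    if (length(sel))
      smr[[paste0(tissue, "_pass")]] <- data.frame(
        gene_id = target_gene[sel], variant_id = cand$id[sel],
        locus_id = sprintf("P%02d", cand$sim_locus[sel]), tissue = tissue,
        p_smr = stats::runif(length(sel), 1e-5, 1e-3),
        p_heidi = stats::runif(length(sel), 0.2, 0.9),
        beta = eff_sign[cand$id[sel]] * stats::runif(length(sel), 0.1, 0.5),
        stringsAsFactors = FALSE)
    fil <- sample(which(!planted[, term]), min(20L, sum(!planted[, term])))
    if (length(fil))
      smr[[paste0(tissue, "_fail")]] <- data.frame(
        gene_id = target_gene[fil], variant_id = cand$id[fil],
        locus_id = sprintf("P%02d", cand$sim_locus[fil]), tissue = tissue,
        p_smr = stats::runif(length(fil), 0.3, 1),
        p_heidi = stats::runif(length(fil), 0.2, 0.9),
        beta = stats::runif(length(fil), -0.2, 0.2),
        stringsAsFactors = FALSE)
  }
  smr <- if (length(smr)) {
    do.call(rbind, c(smr, list(make.row.names = FALSE)))
  } else {
    data.frame(gene_id = character(), variant_id = character(),
               locus_id = character(), tissue = character(),
               p_smr = numeric(), p_heidi = numeric(), beta = numeric(),
               stringsAsFactors = FALSE)
  }

  # --- disruption track: fixed low pattern per window, constant highs at
  # planted windows (see .akita_low_pattern for why this is deterministic)
  offsets <- seq(-100L, 100L, by = 10L)
  low <- .akita_low_pattern()
  ak <- lapply(seq_len(nrow(cand)), function(i) {
    sc <- low
    if (planted[i, "AKITA"]) sc[.akita_high_idx] <- .akita_high_value
    data.frame(chrom = chrom, pos = cand$pos[i] + offsets, score = sc,
               stringsAsFactors = FALSE)
  })
  akita <- do.call(rbind, c(ak, list(make.row.names = FALSE)))
  akita <- akita[order(akita$pos), , drop = FALSE]
  row.names(akita) <- NULL

  # --- ABC and TF score tables per chip cell line (+ fillers)
  tf_names <- c("ZNF460", "CTCF", "PRDM9", "SP1", "KLF5")
  abc <- tfs <- stats::setNames(vector("list", length(cfg$chip_cell_lines)),
                                cfg$chip_cell_lines)
  for (cl in cfg$chip_cell_lines) {
    filler <- data.frame(
      variant_id = sprintf("abcfill%03d", seq_len(cfg$n_filler_scores)),
      gene_id = sprintf("gfill%03d", seq_len(cfg$n_filler_scores)),
      abc_score = stats::runif(cfg$n_filler_scores),
      stringsAsFactors = FALSE)
    sel <- which(planted[, "ABC"])
    abc[[cl]] <- rbind(filler, if (length(sel)) data.frame(
      variant_id = cand$id[sel], gene_id = target_gene[sel],
      abc_score = stats::runif(length(sel), 0.97, 0.995),
      stringsAsFactors = FALSE))
    tfil <- data.frame(
      variant_id = sprintf("tffill%03d", seq_len(cfg$n_filler_scores)),
      tf = sample(tf_names, cfg$n_filler_scores, replace = TRUE),
      score = stats::runif(cfg$n_filler_scores), stringsAsFactors = FALSE)
    tsel <- which(planted[, "TF"])
    tfs[[cl]] <- rbind(tfil, if (length(tsel)) data.frame(
      variant_id = cand$id[tsel],
      tf = sample(tf_names, length(tsel), replace = TRUE),
      score = stats::runif(length(tsel), 0.97, 0.995),
      stringsAsFactors = FALSE))
  }

  # --- TF binding sites track (for the count enrichment)
  tsel <- which(planted[, "TF"])
  fil <- sample(filler_starts, min(12L, length(filler_starts)))
  tf_sites <- data.frame(
    chrom = chrom,
    start = c(cand$pos[tsel] - 1 - 10, fil),
    end = c(cand$pos[tsel] - 1 + 10, fil + 20),
    tf = sample(tf_names, length(tsel) + length(fil), replace = TRUE),
    bound = 1L, stringsAsFactors = FALSE)

  truth <- data.frame(variant_id = cand$id[is_causal],
                      sim_locus = cand$sim_locus[is_causal],
                      gene_id = target_gene[is_causal],
                      planted = vapply(which(is_causal), function(i)
                        paste(.plantable_terms[planted[i, ]], collapse = ","),
                        character(1)),
                      stringsAsFactors = FALSE)

  # --- write everything
  meta <- c(paste("vartier simulate_dataset"),
            paste("seed:", cfg$seed),
            paste("signal_strength:", cfg$signal_strength),
            paste("background_rate:", cfg$background_rate))
  fp <- function(...) file.path(dir, paste0(...))
  paths <- list()
  paths$gwas <- write_meta_tsv(gwas[c("id", "chrom", "pos", "ref", "alt",
                                      "p")], fp("gwas.tsv"), meta)
  paths$ld <- write_meta_tsv(ldtab, fp("ld.tsv"), meta)
  paths$finemap <- write_meta_tsv(finemap, fp("finemap.tsv"), meta)
  paths$mpra <- write_meta_tsv(mpra, fp("mpra.tsv"), meta)
  paths$smr <- write_meta_tsv(smr, fp("smr.tsv"), meta)
  paths$akita <- write_meta_tsv(akita, fp("akita.tsv"), meta)
  paths$genes <- write_meta_tsv(genes[c("gene_id", "chrom", "start", "end",
                                        "tss_pos", "strand")],
                                fp("genes.tsv"), meta)
  paths$tf_sites <- write_meta_tsv(tf_sites, fp("tf_sites.tsv"), meta)
  for (cl in cfg$chip_cell_lines) {
    paths[[paste0("atac_", cl)]] <-
      write_interval_track(atac[[cl]], fp("atac_", cl, ".bed"), meta)
    paths[[paste0("ctcf_", cl)]] <-
      write_interval_track(ctcf[[cl]], fp("ctcf_", cl, ".bed"), meta)
    paths[[paste0("chromhmm_", cl)]] <-
      write_interval_track(chmm[[cl]], fp("chromhmm_", cl, ".bed"), meta)
    paths[[paste0("abc_", cl)]] <-
      write_meta_tsv(abc[[cl]], fp("abc_", cl, ".tsv"), meta)
    paths[[paste0("tfscore_", cl)]] <-
      write_meta_tsv(tfs[[cl]], fp("tfscore_", cl, ".tsv"), meta)
  }
  for (cl in cfg$microc_cell_lines)
    paths[[paste0("microc_", cl)]] <-
      write_interaction_track(microc[[cl]], fp("microc_", cl, ".bedpe"), meta)
  paths$truth <- write_meta_tsv(truth, fp("truth.tsv"), meta)

  invisible(list(paths = paths, truth = truth,
                 data = list(gwas = gwas, ld = ldtab, finemap = finemap,
                             mpra = mpra, smr = smr, akita = akita,
                             genes = genes, atac = atac, ctcf = ctcf,
                             chromhmm = chmm, microc = microc, abc = abc,
                             tfscore = tfs, tf_sites = tf_sites,
                             planted = planted),
                 config = cfg, dir = dir))
}

#' Build the small worked fixture
#'
#' A deterministic 3-locus dataset (no RNG): one fully annotated variant
#' per locus (strong MPRA, ATAC, CTCF, chromatin-state, contact-to-TSS,
#' SMR, disruption, ABC and TF evidence), one partner with partial
#' annotations (one-line MPRA hit plus consistent ATAC peaks), one partner
#' with only a weak chromatin state, and one unannotated partner. Running
#' the pipeline on it makes the annotated variant its locus's sole Tier 1
#' variant and links it strongly to the planted gene.
#'
#' @param dir output directory.
#' @return same structure as [simulate_dataset()].
#' @export
make_worked_fixture <- function(dir = tempfile("worked")) {
  cfg <- sim_config(n_loci = 3L, variants_per_locus = 4L,
                    frac_causal = 1 / 4, signal_strength = 1,
                    background_rate = 0, n_null_variants = 60L,
                    n_filler_scores = 100L, seed = 8880L)
  sim <- simulate_dataset(cfg, dir)
  # add the partial annotations by editing the written tables in place
  gwas <- sim$data$gwas
  part1 <- gwas$id[grepl("^rs3_", gwas$id)]   # first background variant
  part2 <- gwas$id[grepl("^rs4_", gwas$id)]
  mpra <- sim$data$mpra
  sel <- mpra$variant_id %in% part1 & mpra$cell_line == cfg$mpra_cell_lines[1]
  mpra$fdr[sel] <- 0.04
  mpra$log_ratio[sel] <- 0.6
  meta <- c("vartier make_worked_fixture", paste("seed:", cfg$seed))
  write_meta_tsv(mpra, file.path(dir, "mpra.tsv"), meta)
  # pin every partner's P two orders of magnitude above its lead so the
  # whole fixture passes candidate selection deterministically
  for (i in 1:3) {
    lead_p <- gwas$p[gwas$id == sprintf("rs1_%02d", i)]
    bg <- which(gwas$sim_locus == i & gwas$role == "bg")
    gwas$p[bg] <- lead_p * 100
  }
  write_meta_tsv(gwas[c("id", "chrom", "pos", "ref", "alt", "p")],
                 file.path(dir, "gwas.tsv"), meta)
  sim$data$gwas <- gwas
  p1 <- gwas$pos[gwas$id %in% part1] - 1
  p2 <- gwas$pos[gwas$id %in% part2] - 1
  for (cl in cfg$chip_cell_lines) {
    at <- interval_track(c(sim$data$atac[[cl]]$chrom, rep("chr1", length(p1))),
                         c(sim$data$atac[[cl]]$start, p1 - 150),
                         c(sim$data$atac[[cl]]$end, p1 + 150))
    write_interval_track(at, file.path(dir, paste0("atac_", cl, ".bed")), meta)
    ch <- sim$data$chromhmm[[cl]]
    bounds <- sort(unique(c(ch$start, ch$end, p2 - 200, p2 + 200)))
    st <- bounds[-length(bounds)]; en <- bounds[-1]
    lab <- rep("Quies", length(st))
    lab[st %in% (sort(gwas$pos[gwas$role == "causal"]) - 1 - 200)] <- "Enh"
    lab[st %in% (p2 - 200)] <- "EnhWk"
    write_interval_track(interval_track("chr1", st, en, label = lab),
                         file.path(dir, paste0("chromhmm_", cl, ".bed")), meta)
  }
  sim$data$mpra <- mpra
  invisible(sim)
}
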