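# Pipeline orchestration: simulate -> identify -> classify -> de -> targets
# -> enrich -> report, with structured per-stage logging, a MANIFEST of
# output checksums, and a summary report whose arithmetic identities are
# asserted before anything is written.
#
# Stages are always recomputed (no mtime caching): a full synthetic run takes
# seconds, and stale-output bugs are worse than recomputation at this scale.

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used for every stochastic stage.
#' @param simulate If `TRUE`, generate inputs with the synthetic module;
#'   otherwise the `*_path` arguments must point at existing files.
#' @param sim A [sim_config()].  The pipeline default is a demo-scale world
#'   (40 coding genes, 16 lncRNAs on two 150 kb chromosomes, short
#'   transcripts, mass-balanced DE directions) so that the all-vs-all trans
#'   duplex scan stays in the tens of seconds; pass a full `sim_config()`
#'   explicitly for the larger stated world.
#' @param genome_path,reference_path,assembled_path,counts_path,samples_path,pathways_path,scores_path,domains_path
#'   Input files for a non-simulated run (`scores_path`, `domains_path`
#'   optional).
#' @param thresholds Named list overriding any of: `min_length` (200 nt),
#'   `max_orf_aa` (100), `min_fpkm` (1), `fdr` (0.001), `min_abs_log2fc` (1),
#'   `up_kb` (10), `down_kb` (20), `mfe_threshold` (-30), `p_adj` (0.05),
#'   `min_genes` (4).
#' @param prefilter Use the 8-mer seed prefilter in the trans scan.
#' @return List of class `run_config` with defaults resolved.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = TRUE, sim = NULL,
                       genome_path = NULL, reference_path = NULL,
                       assembled_path = NULL, counts_path = NULL,
                       samples_path = NULL, pathways_path = NULL,
                       scores_path = NULL, domains_path = NULL,
                       thresholds = list(), prefilter = TRUE) {
  th <- modifyList(list(min_length = 200, max_orf_aa = 100, min_fpkm = 1,
                        fdr = 0.001, min_abs_log2fc = 1, up_kb = 10,
                        down_kb = 20, mfe_threshold = -30, p_adj = 0.05,
                        min_genes = 4), thresholds)
  if (any(unlist(th[c("min_length", "max_orf_aa", "min_fpkm", "fdr",
                      "min_abs_log2fc", "up_kb", "down_kb", "p_adj",
                      "min_genes")]) <= 0)) {
    .tl_fail("thresholds must be positive (mfe_threshold excepted)")
  }
  if (simulate && is.null(sim)) {
    sim <- sim_config(seed = seed, n_chroms = 2L, chrom_len = 150000L,
                      n_coding = 40L, n_lnc = 16L,
                      coding_len_range = c(500L, 1400L),
                      lnc_len_range = c(200L, 1000L),
                      de_up_prop = 1 / 9, expr_sdlog = 0.4)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim,
                 genome_path = genome_path, reference_path = reference_path,
                 assembled_path = assembled_path, counts_path = counts_path,
                 samples_path = samples_path, pathways_path = pathways_path,
                 scores_path = scores_path, domains_path = domains_path,
                 thresholds = th, prefilter = prefilter),
            class = "run_config")
}

#' Assemble a summary report
#'
#' Derives the headline totals from their components and asserts the
#' arithmetic identities: category counts sum to the lncRNA (isoform) total,
#' up + down = DE total, overlap + window = cis total.
#'
#' @param category_counts Named counts over intergenic / antisense / sense /
#'   intronic.
#' @param de_up,de_down DE transcript counts by direction.
#' @param cis_overlap,cis_window,trans_n Target-pair counts.
#' @param exon_le2 Length-2 vector `c(numerator, denominator)`: transcripts
#'   with at most two exons over all lncRNA isoforms.
#' @param len_lt_1500 Length-2 vector: transcripts shorter than 1500 nt over
#'   all lncRNA isoforms.
#' @param total_assembled,step_counts,sig_pathways Optional provenance
#'   extras.
#' @return List of class `summary_report` with derived fields `lnc_total`,
#'   `de_total`, `cis_total`, `pct_exon_le2` (2 dp), `pct_len_lt_1500`
#'   (2 dp), `pct_category` (2 dp), `pct_antisense_1dp` (1 dp).
#' @export
summary_report <- function(category_counts, de_up, de_down, cis_overlap,
                           cis_window, trans_n, exon_le2, len_lt_1500,
                           total_assembled = NA_integer_, step_counts = NULL,
                           sig_pathways = NA_integer_) {
  cats <- c("intergenic", "antisense", "sense", "intronic")
  if (!setequal(names(category_counts), cats)) {
    .tl_fail("summary_report: category_counts must name the four categories")
  }
  category_counts <- category_counts[cats]
  lnc_total <- sum(category_counts)
  de_total <- de_up + de_down
  cis_total <- cis_overlap + cis_window
  if (exon_le2[2L] != lnc_total || len_lt_1500[2L] != lnc_total) {
    .tl_fail("summary_report: share denominators must equal the lncRNA total")
  }
  structure(list(
    category_counts = category_counts, lnc_total = lnc_total,
    de_up = de_up, de_down = de_down, de_total = de_total,
    cis_overlap = cis_overlap, cis_window = cis_window, cis_total = cis_total,
    trans_n = trans_n, exon_le2 = exon_le2, len_lt_1500 = len_lt_1500,
    pct_category = vapply(category_counts, percent_share, 0, den = lnc_total),
    pct_antisense_1dp = percent_share(category_counts[["antisense"]],
                                      lnc_total, 1L),
    pct_exon_le2 = percent_share(exon_le2[1L], exon_le2[2L], 2L),
    pct_len_lt_1500 = percent_share(len_lt_1500[1L], len_lt_1500[2L], 2L),
    total_assembled = total_assembled, step_counts = step_counts,
    sig_pathways = sig_pathways), class = "summary_report")
}

#' Render a summary report
#'
#' Re-checks every arithmetic identity at render time (a report that does
#' not add up is a hard failure, never silently reconciled) and produces
#' human-readable text plus a machine-readable table.
#'
#' @param report A [summary_report()].
#' @return List with `text` (character vector of lines) and `table`
#'   (data.frame `metric` / `value`), invisibly also re-exposing the report.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "summary_report"))
  with(report, {
    if (sum(category_counts) != lnc_total ||
        de_up + de_down != de_total ||
        cis_overlap + cis_window != cis_total) {
      .tl_fail("summary report fails its arithmetic identities")
    }
  })
  cc <- report$category_counts
  text <- c(
    sprintf("lncRNA isoforms: %d", report$lnc_total),
    sprintf("  intergenic %d (%.2f%%), antisense %d (%.2f%%, %.1f%% at 1 dp), sense %d (%.2f%%), intronic %d (%.2f%%)",
            cc[["intergenic"]], report$pct_category[["intergenic"]],
            cc[["antisense"]], report$pct_category[["antisense"]],
            report$pct_antisense_1dp,
            cc[["sense"]], report$pct_category[["sense"]],
            cc[["intronic"]], report$pct_category[["intronic"]]),
    sprintf("  <= 2 exons: %d/%d (%.2f%%)", report$exon_le2[1L],
            report$exon_le2[2L], report$pct_exon_le2),
    sprintf("  < 1500 nt: %d/%d (%.2f%%)", report$len_lt_1500[1L],
            report$len_lt_1500[2L], report$pct_len_lt_1500),
    sprintf("DE lncRNAs: %d (up %d, down %d)", report$de_total, report$de_up,
            report$de_down),
    sprintf("cis pairs: %d (overlap %d, window %d)", report$cis_total,
            report$cis_overlap, report$cis_window),
    sprintf("trans pairs: %d", report$trans_n),
    sprintf("significant pathways: %s", report$sig_pathways))
  table <- data.frame(
    metric = c("lnc_total", "intergenic", "antisense", "sense", "intronic",
               "pct_antisense_1dp", "pct_exon_le2", "pct_len_lt_1500",
               "de_up", "de_down", "de_total", "cis_overlap", "cis_window",
               "cis_total", "trans_n", "sig_pathways"),
    value = c(report$lnc_total, cc[["intergenic"]], cc[["antisense"]],
              cc[["sense"]], cc[["intronic"]], report$pct_antisense_1dp,
              report$pct_exon_le2, report$pct_len_lt_1500, report$de_up,
              report$de_down, report$de_total, report$cis_overlap,
              report$cis_window, report$cis_total, report$trans_n,
              report$sig_pathways),
    stringsAsFactors = FALSE)
  invisible(list(text = text, table = table, report = report))
}

.stage_log <- function(stage, ...) {
  message(sprintf("[thermolnc] %-9s %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' @param config A [run_config()].
#' @return The [summary_report()], invisibly; all stage outputs are written
#'   under `config$out_dir` together with `MANIFEST.tsv` (per-file md5) and
#'   `config_echo.txt` (the resolved configuration).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }

  # any failure stops the run with the stage named; outputs written so far
  # are retained, and the MANIFEST marks the incomplete stage
  stage_now <- "init"
  invisible(tryCatch({

  # ---- inputs
  stage_now <- if (config$simulate) "simulate" else "input"
  if (config$simulate) {
    sim <- simulate_genome(config$sim)
    expr <- simulate_counts(c(sim$reference, sim$assembled), sim$truth, config$sim)
    set.seed(config$seed + 2L)
    pmap <- simulate_pathway_map(vapply(sim$reference, `[[`, "", "gene_id"))
    sdir <- file.path(out, "simulate")
    write_simulation(sim, sdir, expr = expr, pathway_map = pmap)
    for (f in list.files(sdir, full.names = TRUE)) note("simulate", f)
    genome <- sim$genome; reference <- sim$reference; assembled <- sim$assembled
    .stage_log("simulate", "%d reference genes, %d assembled transcripts",
               length(reference), length(assembled))
  } else {
    genome <- read_fasta(config$genome_path)
    reference <- read_gtf(config$reference_path, coding_only = TRUE)
    assembled <- read_gtf(config$assembled_path)
    counts <- read_counts_table(config$counts_path)
    samp <- read_samples_table(config$samples_path)
    all_models <- c(reference, assembled)
    lens <- setNames(vapply(all_models, spliced_length, 0),
                     vapply(all_models, `[[`, "", "transcript_id"))
    expr <- expression_matrix(counts, samp$condition[match(colnames(counts),
                                                           samp$sample_id)],
                              samp$library_size[match(colnames(counts),
                                                      samp$sample_id)],
                              lengths = lens[rownames(counts)])
    pmap <- if (is.null(config$pathways_path)) NULL
            else read_pathway_map(config$pathways_path)
    .stage_log("input", "%d reference genes, %d assembled transcripts",
               length(reference), length(assembled))
  }
  scores <- if (is.null(config$scores_path)) NULL
            else read_scores_table(config$scores_path)
  domains <- if (is.null(config$domains_path)) NULL
             else read_domain_hits(config$domains_path)

  # ---- identify
  stage_now <- "identify"
  set.seed(config$seed + 3L)  # hexamer-background shuffle
  asm_ids <- vapply(assembled, `[[`, "", "transcript_id")
  expr_asm <- expression_matrix(expr$counts[asm_ids, , drop = FALSE],
                                expr$condition, expr$library_size,
                                lengths = expr$lengths)
  casc <- apply_filter_cascade(assembled, reference, genome, expr_asm,
                               scores = scores, domain_hits = domains,
                               thresholds = list(min_length = th$min_length,
                                                 max_orf_aa = th$max_orf_aa,
                                                 min_fpkm = th$min_fpkm))
  idir <- file.path(out, "identify")
  dir.create(idir, showWarnings = FALSE)
  write_gtf(casc$lncrna, file.path(idir, "lncrna.gtf"))
  write_tsv(casc$trace, file.path(idir, "filter_trace.tsv"))
  write_tsv(casc$step_counts, file.path(idir, "step_counts.tsv"))
  for (f in list.files(idir, full.names = TRUE)) note("identify", f)
  .stage_log("identify", "%d of %d assembled transcripts pass the cascade",
             length(casc$lncrna), length(assembled))

  # ---- classify
  stage_now <- "classify"
  index <- build_gene_index(reference)
  records <- classify_lncrnas(casc$lncrna, index)
  cat_tab <- category_summary(records)
  cdir <- file.path(out, "classify")
  dir.create(cdir, showWarnings = FALSE)
  write_tsv(data.frame(
    transcript_id = vapply(records, function(r) r$model$transcript_id, ""),
    category = vapply(records, `[[`, "", "category"),
    evidence = vapply(records, `[[`, "", "evidence"),
    stringsAsFactors = FALSE), file.path(cdir, "categories.tsv"))
  write_tsv(cat_tab, file.path(cdir, "category_counts.tsv"))
  for (f in list.files(cdir, full.names = TRUE)) note("classify", f)
  .stage_log("classify", paste(cat_tab$count, collapse = "/"))

  # ---- differential expression (all transcripts with counts)
  stage_now <- "de"
  de <- call_de(expr, fdr_threshold = th$fdr,
                min_abs_log2fc = th$min_abs_log2fc)
  fpkm <- compute_fpkm(expr)
  ddir <- file.path(out, "de")
  dir.create(ddir, showWarnings = FALSE)
  write_tsv(data.frame(transcript_id = rownames(fpkm), round(fpkm, 4),
                       check.names = FALSE), file.path(ddir, "fpkm.tsv"))
  write_tsv(de, file.path(ddir, "de_results.tsv"))
  lnc_ids <- vapply(casc$lncrna, `[[`, "", "transcript_id")
  de_lnc_tab <- de[de$transcript_id %in% lnc_ids & de$status != "ns", ]
  ref_ids <- vapply(reference, `[[`, "", "transcript_id")
  de_gene_tab <- de[de$transcript_id %in% ref_ids & de$status != "ns", ]
  write_tsv(data.frame(
    set = c("lncRNA_up", "lncRNA_down", "gene_up", "gene_down"),
    n = c(sum(de_lnc_tab$status == "up"), sum(de_lnc_tab$status == "down"),
          sum(de_gene_tab$status == "up"), sum(de_gene_tab$status == "down")),
    stringsAsFactors = FALSE), file.path(ddir, "de_summary.tsv"))
  for (f in list.files(ddir, full.names = TRUE)) note("de", f)
  .stage_log("de", "%d DE lncRNAs, %d DE genes", nrow(de_lnc_tab),
             nrow(de_gene_tab))

  # ---- targets
  stage_now <- "targets"
  de_lnc_models <- casc$lncrna[lnc_ids %in% de_lnc_tab$transcript_id]
  de_mrna_models <- reference[ref_ids %in% de_gene_tab$transcript_id]
  cis <- find_cis_pairs(de_lnc_models, de_mrna_models,
                        up_kb = th$up_kb, down_kb = th$down_kb)
  trans <- find_trans_pairs(de_lnc_models, de_mrna_models, genome,
                            energy_threshold = th$mfe_threshold,
                            cis_pairs = cis, prefilter = config$prefilter)
  tdir <- file.path(out, "targets")
  dir.create(tdir, showWarnings = FALSE)
  write_tsv(cis, file.path(tdir, "cis_pairs.tsv"))
  write_tsv(trans, file.path(tdir, "trans_pairs.tsv"))
  for (f in list.files(tdir, full.names = TRUE)) note("targets", f)
  .stage_log("targets", "%d cis pairs, %d trans pairs", nrow(cis), nrow(trans))

  # ---- enrichment (cis-regulated DE target genes)
  stage_now <- "enrich"
  gene_of <- setNames(vapply(reference, `[[`, "", "gene_id"), ref_ids)
  target_genes <- unique(gene_of[unique(c(cis$mrna_id, trans$mrna_id))])
  enr <- if (!is.null(pmap) && length(target_genes)) {
    enrich_pathways(target_genes, pmap, p_adj_threshold = th$p_adj,
                    min_genes = th$min_genes)
  } else {
    enrich_pathways(character(0), if (is.null(pmap))
      data.frame(gene_id = "g", pathway_id = "p", pathway_name = "p",
                 stringsAsFactors = FALSE) else pmap)
  }
  edir <- file.path(out, "enrich")
  dir.create(edir, showWarnings = FALSE)
  write_tsv(enr, file.path(edir, "enrichment.tsv"))
  for (f in list.files(edir, full.names = TRUE)) note("enrich", f)
  .stage_log("enrich", "%d pathways tested, %d significant", nrow(enr),
             sum(enr$significant))

  # ---- report
  stage_now <- "report"
  lnc_models <- casc$lncrna
  nex <- vapply(lnc_models, function(m) nrow(m$exons), 0L)
  lens <- vapply(lnc_models, spliced_length, 0)
  counts_by_cat <- setNames(cat_tab$count, cat_tab$category)
  report <- summary_report(
    category_counts = counts_by_cat,
    de_up = sum(de_lnc_tab$status == "up"),
    de_down = sum(de_lnc_tab$status == "down"),
    cis_overlap = sum(cis$mode == "cis_overlap"),
    cis_window = sum(cis$mode == "cis_window"),
    trans_n = nrow(trans),
    exon_le2 = c(sum(nex <= 2L), length(lnc_models)),
    len_lt_1500 = c(sum(lens < 1500), length(lnc_models)),
    total_assembled = length(assembled), step_counts = casc$step_counts,
    sig_pathways = sum(enr$significant))
  rendered <- render_report(report)
  rdir <- file.path(out, "report")
  dir.create(rdir, showWarnings = FALSE)
  writeLines(rendered$text, file.path(rdir, "summary.txt"))
  write_tsv(rendered$table, file.path(rdir, "summary.tsv"))
  for (f in list.files(rdir, full.names = TRUE)) note("report", f)

  # ---- manifest + config echo
  cfg_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("simulate: %s", config$simulate),
                 sprintf("prefilter: %s", config$prefilter),
                 vapply(names(th), function(k) sprintf("%s: %s", k, th[[k]]), ""))
  writeLines(cfg_lines, file.path(out, "config_echo.txt"))
  write_tsv(do.call(rbind, manifest), file.path(out, "MANIFEST.tsv"))
  report

  }, error = function(e) {
    man <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(stage = character(0), file = character(0), md5 = character(0))
    man <- rbind(man, data.frame(stage = stage_now, file = "(incomplete)",
                                 md5 = "FAILED", stringsAsFactors = FALSE))
    write_tsv(man, file.path(out, "MANIFEST.tsv"))
    .tl_fail("stage '%s' failed: %s", stage_now, conditionMessage(e))
  }))
}
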