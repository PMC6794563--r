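# Synthetic transcriptome with planted ground truth.
#
# The generator emits a toy genome, a coding reference annotation, an
# "assembled" transcript set (re-discovered coding models plus lncRNA
# candidates of all four genomic-context categories), and a negative-binomial
# count matrix with a planted DE fraction.  Placement is constructive:
# every planted lncRNA has an unambiguous context, so category recovery by
# the classifier is exact.  Coding CDS sequences are drawn from a strongly
# biased codon-usage table so the hexamer surrogate has signal; lncRNA
# sequences are uniform, with any ORF longer than 100 aa broken by in-frame
# stop-codon injection (never inside a host CDS).
#
# RNG contract: simulate_genome() uses one stream seeded with `seed` (draw
# order: lnc structures -> gene structures -> placement -> expression truth);
# simulate_counts() uses a separate stream seeded with `seed + 1`.

# standard genetic code, DNA alphabet; used for the biased codon table
.GENETIC_CODE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# fixed "highly expressed gene"-style usage: within each amino acid the
# alphabetically first codon carries weight 0.9, the rest share 0.1 (strong
# bias of the kind seen in highly expressed fungal genes; this is what gives
# the hexamer surrogate its discriminative signal)
.codon_usage <- function() {
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  w <- setNames(numeric(length(sense)), sense)
  for (aa in unique(.GENETIC_CODE[sense])) {
    cods <- sort(sense[.GENETIC_CODE[sense] == aa])
    if (length(cods) == 1L) { w[cods] <- 1; next }
    w[cods[1L]] <- 0.9
    w[cods[-1L]] <- 0.1 / (length(cods) - 1L)
  }
  w
}

#' Largest-remainder integer allocation of proportions
#' @param props Named proportions summing to 1.
#' @param n Total to allocate.
#' @return Named integer vector summing to `n`.
#' @export
allocate_counts <- function(props, n) {
  base <- floor(props * n)
  rem <- props * n - base
  left <- n - sum(base)
  if (left > 0) {
    o <- order(-rem, seq_along(rem))
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(props))
}

#' Simulation configuration
#'
#' Defaults state the emulated world: roughly six coding genes per lncRNA,
#' lncRNAs shorter than mRNAs (200-2100 nt spliced, so about 68% fall below
#' 1500 nt, vs 500-2400 nt for coding), at most two exons, context
#' proportions close to the four-category split reported for fungal
#' heat-stress lncRNA sets (81/16/2/1), expression a fifth of the coding
#' level, a planted DE fraction with |log2FC| = 3, and negative-binomial
#' dispersion 0.05.
#'
#' @param seed Integer RNG seed.
#' @param n_chroms,chrom_len Genome shape.
#' @param n_coding,n_lnc Locus counts.
#' @param category_props Named proportions over intergenic / antisense /
#'   sense / intronic, summing to 1.
#' @param lnc_len_range,coding_len_range Spliced-length ranges (nt).
#' @param lnc_exon_max Max exons per lncRNA (default 2).
#' @param coding_exon_range Exon-count range for coding genes.
#' @param de_fraction,de_log2fc,de_up_prop Planted DE fraction, effect size,
#'   and share of DE transcripts that go up under heat.
#' @param nb_dispersion NB dispersion phi (variance m + phi m^2).
#' @param libsize_range Range for the per-sample unassigned-fragment margin
#'   added to the column sum to form the library size.  Keep it small
#'   relative to the assigned fragments: a margin comparable to the column
#'   sum shifts every FPKM in that sample and masquerades as fold change.
#' @param n_reps_per_condition Replicates per condition (default 3).
#' @param lnc_expr_scale,coding_mean_log,expr_sdlog Log-normal baseline-mean
#'   model: coding means ~ lognormal(coding_mean_log, expr_sdlog); lncRNA
#'   means are scaled by `lnc_expr_scale`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_len = 600000L,
                       n_coding = 480L, n_lnc = 80L,
                       category_props = c(intergenic = 0.81, antisense = 0.16,
                                          sense = 0.02, intronic = 0.01),
                       lnc_len_range = c(200L, 2100L),
                       coding_len_range = c(500L, 2400L),
                       lnc_exon_max = 2L, coding_exon_range = c(1L, 4L),
                       de_fraction = 0.3, de_log2fc = 3, de_up_prop = 0.67,
                       nb_dispersion = 0.05,
                       libsize_range = c(2000L, 6000L),
                       n_reps_per_condition = 3L,
                       lnc_expr_scale = 0.2, coding_mean_log = log(300),
                       expr_sdlog = 0.8) {
  cats <- c("intergenic", "antisense", "sense", "intronic")
  if (!setequal(names(category_props), cats)) {
    .tl_fail("category_props must name exactly: %s", paste(cats, collapse = ", "))
  }
  category_props <- category_props[cats]
  if (abs(sum(category_props) - 1) > 1e-9) .tl_fail("category_props must sum to 1")
  if (any(c(n_chroms, chrom_len, n_coding, n_lnc, n_reps_per_condition) < 1)) {
    .tl_fail("all counts must be >= 1")
  }
  if (de_log2fc <= 0) .tl_fail("de_log2fc must be > 0")
  if (nb_dispersion <= 0) .tl_fail("nb_dispersion must be > 0")
  if (de_fraction < 0 || de_fraction > 1) .tl_fail("de_fraction in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

# sense-order genomic positions (1-based) of a spliced transcript
.spliced_positions <- function(exons, strand) {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq.int(exons[i, 1L] + 1L, exons[i, 2L])
  }))
  if (strand == "-") rev(pos) else pos
}

# compress sorted 1-based positions into 0-based half-open intervals
.positions_to_intervals <- function(pos) {
  pos <- sort(pos)
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  t(vapply(seq_len(length(brk) - 1L), function(i) {
    c(pos[brk[i] + 1L] - 1L, pos[brk[i + 1L]])
  }, numeric(2)))
}

#' Simulate a genome with planted coding genes and lncRNAs
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector), `reference` (coding
#'   [transcript_model()]s with CDS), `assembled` (re-discovered coding
#'   models plus lncRNA candidates, exon structures only), `truth`
#'   (data.frame: `transcript_id`, `gene_id`, `ref_gene_id`, `true_class`,
#'   `true_de_status`, `true_log2fc`, `true_mean`), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cats <- c("intergenic", "antisense", "sense", "intronic")
  ncat <- allocate_counts(config$category_props, config$n_lnc)
  lnc_cat <- rep(cats, times = ncat)
  n_host <- sum(ncat[c("antisense", "sense", "intronic")])
  if (n_host > config$n_coding) {
    .tl_fail("need %d host genes but only %d coding genes", n_host, config$n_coding)
  }

  # ---- lncRNA structural draws
  lr <- config$lnc_len_range
  lnc <- lapply(seq_len(config$n_lnc), function(i) {
    cat <- lnc_cat[i]
    len <- sample(lr[1L]:lr[2L], 1L)
    nex <- if (cat %in% c("antisense", "sense")) 1L
           else sample(seq_len(config$lnc_exon_max), 1L)
    if (nex == 2L && len < 160L) nex <- 1L
    e1 <- ilen <- NA_integer_
    if (nex == 2L) {
      e1 <- sample(80:(len - 80L), 1L)
      ilen <- sample(40:80, 1L)
    }
    ovl <- if (cat %in% c("antisense", "sense"))
      sample(40:min(150L, len - 60L), 1L) else NA_integer_
    list(cat = cat, len = len, nex = nex, e1 = e1, ilen = ilen, ovl = ovl,
         span = if (nex == 2L) len + ilen else len)
  })

  # host assignment: genes 1..n_anti host antisense, then sense, then intronic
  host_role <- rep("none", config$n_coding)
  host_lnc <- rep(NA_integer_, config$n_coding)
  hosted <- which(lnc_cat != "intergenic")
  for (g in seq_along(hosted)) {
    host_role[g] <- lnc_cat[hosted[g]]
    host_lnc[g] <- hosted[g]
  }

  # ---- coding gene structural draws
  cr <- config$coding_len_range
  exr <- config$coding_exon_range
  genes <- lapply(seq_len(config$n_coding), function(g) {
    target <- round(runif(1L, cr[1L], cr[2L]))
    utr5 <- sample(20:60, 1L); utr3 <- sample(20:80, 1L)
    aa <- max(110L, (target - utr5 - utr3 - 3L) %/% 3L)
    cds_nt <- 3L * aa + 3L
    spliced <- utr5 + cds_nt + utr3
    k <- sample(exr[1L]:exr[2L], 1L)
    if (host_role[g] == "intronic") k <- max(k, 2L)
    k <- max(1L, min(k, (spliced - 250L) %/% 80L + 1L))
    if (host_role[g] == "intronic") k <- max(k, 2L)
    exlens <- c(250L, rep(80L, k - 1L))
    leftover <- spliced - sum(exlens)
    if (leftover > 0L) {
      add <- as.integer(stats::rmultinom(1L, leftover, rep(1, k)))
      exlens <- exlens + add
    }
    intlens <- if (k > 1L) sample(60:300, k - 1L, replace = TRUE) else integer(0)
    if (host_role[g] == "intronic") {
      intlens[1L] <- lnc[[host_lnc[g]]]$span + 120L
    }
    strand <- sample(c("+", "-"), 1L)
    list(utr5 = utr5, utr3 = utr3, aa = aa, cds_nt = cds_nt, spliced = spliced,
         exlens = exlens, intlens = intlens, strand = strand,
         span = spliced + sum(intlens))
  })

  # ---- placement
  jobs <- c(lapply(seq_len(config$n_coding), function(g) list(type = "gene", idx = g)),
            lapply(which(lnc_cat == "intergenic"),
                   function(i) list(type = "lnc", idx = i)))
  jobs <- jobs[sample(length(jobs))]
  cursors <- rep(1000, config$n_chroms)
  chrom_ids <- sprintf("chr%d", seq_len(config$n_chroms))
  gene_pos <- integer(config$n_coding); gene_chr <- integer(config$n_coding)
  lnc_pos <- integer(config$n_lnc); lnc_chr <- integer(config$n_lnc)
  lnc_strand <- character(config$n_lnc)
  total_need <- 0
  for (job in jobs) {
    if (job$type == "gene") {
      g <- job$idx
      ext <- if (host_role[g] %in% c("antisense", "sense")) {
        li <- lnc[[host_lnc[g]]]; li$len - li$ovl
      } else 0L
      env_len <- ext + genes[[g]]$span
    } else {
      ext <- 0L
      env_len <- lnc[[job$idx]]$span
    }
    gap <- sample(600:1200, 1L)
    if (ext > 0L) gap <- max(gap, ext + 100L)
    total_need <- total_need + gap + env_len
    placed <- FALSE
    for (ci in order(cursors)) {
      start <- cursors[ci] + gap
      if (start + env_len + 1000 <= config$chrom_len) {
        cursors[ci] <- start + env_len
        if (job$type == "gene") {
          gene_pos[job$idx] <- start + ext  # gene body starts after the lnc extension
          gene_chr[job$idx] <- ci
        } else {
          lnc_pos[job$idx] <- start
          lnc_chr[job$idx] <- ci
        }
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      .tl_fail("genome too small for the requested loci; suggest chrom_len >= %d",
               ceiling(1.3 * total_need / config$n_chroms) + 2000)
    }
  }

  # ---- models
  reference <- vector("list", config$n_coding)
  asm_coding <- vector("list", config$n_coding)
  for (g in seq_len(config$n_coding)) {
    gn <- genes[[g]]
    k <- length(gn$exlens)
    starts <- gene_pos[g] + cumsum(c(0L, head(gn$exlens, -1L) + gn$intlens))
    exons <- cbind(starts, starts + gn$exlens)
    pos <- .spliced_positions(exons, gn$strand)
    cds_pos <- pos[(gn$utr5 + 1L):(gn$utr5 + gn$cds_nt)]
    cds_iv <- .positions_to_intervals(cds_pos)
    reference[[g]] <- transcript_model(
      sprintf("ref_t%04d", g), sprintf("ref_g%04d", g), chrom_ids[gene_chr[g]],
      gn$strand, exons, cds = cds_iv, biotype = "coding", source = "thermolnc_sim")
    asm_coding[[g]] <- transcript_model(
      sprintf("asm_c%04d", g), sprintf("asm_gc%04d", g), chrom_ids[gene_chr[g]],
      gn$strand, exons, biotype = "assembled", source = "thermolnc_sim")
  }
  asm_lnc <- vector("list", config$n_lnc)
  for (i in seq_len(config$n_lnc)) {
    li <- lnc[[i]]
    if (li$cat %in% c("antisense", "sense")) {
      g <- which(host_lnc == i)
      gstrand <- genes[[g]]$strand
      lnc_strand[i] <- if (li$cat == "antisense") setdiff(c("+", "-"), gstrand)
                       else gstrand
      start <- gene_pos[g] - (li$len - li$ovl)
      exons <- cbind(start, start + li$len)
      lnc_chr[i] <- gene_chr[g]
    } else if (li$cat == "intronic") {
      g <- which(host_lnc == i)
      intron_start <- gene_pos[g] + genes[[g]]$exlens[1L]
      start <- intron_start + 60L
      lnc_strand[i] <- sample(c("+", "-"), 1L)
      exons <- if (li$nex == 2L) {
        cbind(c(start, start + li$e1 + li$ilen),
              c(start + li$e1, start + li$span))
      } else cbind(start, start + li$len)
      lnc_chr[i] <- gene_chr[g]
    } else {
      start <- lnc_pos[i]
      lnc_strand[i] <- sample(c("+", "-"), 1L)
      exons <- if (li$nex == 2L) {
        cbind(c(start, start + li$e1 + li$ilen),
              c(start + li$e1, start + li$span))
      } else cbind(start, start + li$len)
    }
    asm_lnc[[i]] <- transcript_model(
      sprintf("asm_l%04d", i), sprintf("asm_gl%04d", i), chrom_ids[lnc_chr[i]],
      lnc_strand[i], exons, biotype = "lncRNA_candidate", source = "thermolnc_sim")
  }

  # ---- sequences
  bases <- c("A", "C", "G", "T")
  chrom_chars <- lapply(seq_len(config$n_chroms), function(ci) {
    sample(bases, config$chrom_len, replace = TRUE)
  })
  cds_mask <- lapply(seq_len(config$n_chroms), function(ci) {
    logical(config$chrom_len)
  })
  usage <- .codon_usage()
  sense_codons <- names(usage)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (g in seq_len(config$n_coding)) {
    gn <- genes[[g]]; m <- reference[[g]]
    codons <- sample(sense_codons, gn$aa - 1L, replace = TRUE, prob = usage)
    cds_seq <- paste0("ATG", paste(codons, collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    pos <- .spliced_positions(m$exons, m$strand)
    cds_pos <- pos[(gn$utr5 + 1L):(gn$utr5 + gn$cds_nt)]
    chars <- strsplit(cds_seq, "")[[1]]
    if (m$strand == "-") chars <- unname(comp[chars])
    ci <- gene_chr[g]
    chrom_chars[[ci]][cds_pos] <- chars
    cds_mask[[ci]][cds_pos] <- TRUE
  }

  # ---- lncRNA ORF suppression (stop-codon injection outside any CDS)
  for (i in seq_len(config$n_lnc)) {
    m <- asm_lnc[[i]]
    ci <- lnc_chr[i]
    pos <- .spliced_positions(m$exons, m$strand)
    for (iter in 1:200) {
      sense <- chrom_chars[[ci]][pos]
      if (m$strand == "-") sense <- unname(comp[sense])
      orf <- longest_orf_aa(dna_to_rna(paste(sense, collapse = "")))
      if (orf$length_aa <= 100L) break
      cand <- seq.int(orf$start + 3L, orf$end - 6L, by = 3L)
      ok <- vapply(cand, function(p) {
        !any(cds_mask[[ci]][pos[(p + 1L):(p + 3L)]])
      }, TRUE)
      cand <- cand[ok]
      if (length(cand) == 0L) .tl_fail("internal: no stop-injection site for %s",
                                       m$transcript_id)
      mid <- (orf$start + orf$end) / 2
      p <- cand[which.min(abs(cand - mid))]
      chars <- c("T", "A", "A")
      if (m$strand == "-") chars <- unname(comp[chars])
      chrom_chars[[ci]][pos[(p + 1L):(p + 3L)]] <- chars
    }
  }
  genome <- setNames(vapply(chrom_chars, paste, "", collapse = ""), chrom_ids)

  # ---- expression / DE truth (one draw per molecule; shared by the
  #      reference transcript and its assembled duplicate)
  n_mol <- config$n_coding + config$n_lnc
  is_de <- runif(n_mol) < config$de_fraction
  dir_up <- runif(n_mol) < config$de_up_prop
  base_mean <- rlnorm(n_mol, config$coding_mean_log, config$expr_sdlog)
  status <- ifelse(is_de, ifelse(dir_up, "up", "down"), "null")
  lfc <- ifelse(is_de, ifelse(dir_up, config$de_log2fc, -config$de_log2fc), 0)
  truth_rows <- list()
  for (g in seq_len(config$n_coding)) {
    for (id in c(sprintf("ref_t%04d", g), sprintf("asm_c%04d", g))) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = id,
        gene_id = if (startsWith(id, "ref")) sprintf("ref_g%04d", g)
                  else sprintf("asm_gc%04d", g),
        ref_gene_id = sprintf("ref_g%04d", g),
        true_class = "coding", true_de_status = status[g],
        true_log2fc = lfc[g], true_mean = base_mean[g],
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(config$n_lnc)) {
    k <- config$n_coding + i
    host <- which(host_lnc == i)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      transcript_id = sprintf("asm_l%04d", i),
      gene_id = sprintf("asm_gl%04d", i),
      ref_gene_id = if (length(host)) sprintf("ref_g%04d", host) else "none",
      true_class = paste0("lnc:", lnc_cat[i]), true_de_status = status[k],
      true_log2fc = lfc[k],
      true_mean = base_mean[k] * config$lnc_expr_scale,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)

  list(genome = genome, reference = reference,
       assembled = c(asm_coding, asm_lnc), truth = truth, config = config)
}

#' Simulate a fragment-count matrix from planted truth
#'
#' Per-transcript baseline mean from the truth table; heat-condition mean =
#' baseline * 2^(true_log2fc); counts negative-binomial with variance
#' `m + phi m^2`; per-sample library size = column sum plus an
#' unassigned-fragment margin drawn from `libsize_range`.  Uses its own RNG
#' stream seeded with `config$seed + 1`.
#'
#' @param models List of [transcript_model()]s to emit counts for.
#' @param truth Truth data.frame covering all of `models` (see
#'   [simulate_genome()]).
#' @param config A [sim_config()].
#' @return An [expression_matrix()] with lengths attached.
#' @export
simulate_counts <- function(models, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ids <- vapply(models, `[[`, "", "transcript_id")
  missing <- setdiff(ids, truth$transcript_id)
  if (length(missing)) .tl_fail("truth does not cover transcript %s", missing[1L])
  tr <- truth[match(ids, truth$transcript_id), ]
  nrep <- config$n_reps_per_condition
  samples <- c(sprintf("ctrl_%d", seq_len(nrep)), sprintf("heat_%d", seq_len(nrep)))
  condition <- rep(c("control", "heat"), each = nrep)
  mu_ctrl <- tr$true_mean
  mu_heat <- tr$true_mean * 2^tr$true_log2fc
  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = length(ids), ncol = 2L * nrep,
                   dimnames = list(ids, samples))
  for (r in seq_len(nrep)) {
    counts[, r] <- rnbinom(length(ids), mu = mu_ctrl, size = size)
    counts[, nrep + r] <- rnbinom(length(ids), mu = mu_heat, size = size)
  }
  lr <- config$libsize_range
  margin <- sample(lr[1L]:lr[2L], 2L * nrep, replace = TRUE)
  lengths <- setNames(vapply(models, spliced_length, 0), ids)
  expression_matrix(counts, condition,
                    library_size = colSums(counts) + margin,
                    lengths = lengths)
}

#' Random gene-to-pathway membership map
#'
#' Assigns each gene to one to three of `n_pathways` pathways uniformly
#' (plain plumbing for the enrichment stage; no planted signal).  Uses the
#' current RNG stream.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_pathways Number of pathways.
#' @return data.frame with `gene_id`, `pathway_id`, `pathway_name`.
#' @export
simulate_pathway_map <- function(gene_ids, n_pathways = 15L) {
  rows <- lapply(gene_ids, function(g) {
    pw <- sample(n_pathways, sample(1:3, 1L))
    data.frame(gene_id = g, pathway_id = sprintf("pw%02d", pw),
               pathway_name = sprintf("Synthetic pathway %02d", pw),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `assembled.gtf`, `truth.tsv` and,
#' when given, `counts.tsv`, `samples.tsv`, `pathways.tsv`.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @param expr Optional [expression_matrix()] from [simulate_counts()].
#' @param pathway_map Optional data.frame from [simulate_pathway_map()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, expr = NULL, pathway_map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$reference, file.path(dir, "annotation.gtf"))
  write_gtf(sim$assembled, file.path(dir, "assembled.gtf"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  if (!is.null(expr)) {
    cdf <- data.frame(transcript_id = rownames(expr$counts), expr$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(cdf, file.path(dir, "counts.tsv"))
    write_tsv(data.frame(sample_id = expr$sample_ids,
                         condition = unname(expr$condition),
                         library_size = unname(expr$library_size),
                         stringsAsFactors = FALSE),
              file.path(dir, "samples.tsv"))
  }
  if (!is.null(pathway_map)) write_tsv(pathway_map, file.path(dir, "pathways.tsv"))
  invisible(dir)
}
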