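# File formats and core containers.
#
# Conventions used throughout the package:
#   * GTF on disk is 1-based inclusive; every internal interval is 0-based
#     half-open [start, end).  Conversion happens exactly once, at read/write.
#   * Exons are stored ascending by genomic start for both strands; strand is
#     applied at sequence-extraction time (reverse complement for "-").
#   * The genome is DNA (T); transcript sequences handed to the duplex module
#     are RNA (U) by plain substitution.

# ---------------------------------------------------------------- sequences

#' Read a FASTA file
#'
#' Strict reader for uncompressed FASTA: records in file order, sequences
#' upper-cased and line-wrapping joined.  Duplicate ids, empty records and
#' characters outside `A,C,G,T,U,N` are rejected with the offending line
#' number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .tl_fail("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) .tl_fail("empty FASTA file: %s", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) .tl_fail("line %d: expected FASTA header", line_no[1L])
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    .tl_fail("line %d: empty FASTA id", line_no[is_hdr][which(!nzchar(ids))[1L]])
  }
  if (anyDuplicated(ids)) {
    .tl_fail("duplicate id '%s' in %s", ids[duplicated(ids)][1L], path)
  }
  grp <- cumsum(is_hdr)
  bad <- grep("[^ACGTUNacgtun]", lines[!is_hdr])
  if (length(bad)) {
    .tl_fail("line %d: illegal sequence character", line_no[!is_hdr][bad[1L]])
  }
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste, "", collapse = "")
  out <- setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- toupper(seqs)
  if (any(nchar(out) < 1L)) {
    .tl_fail("record '%s' has no sequence", ids[which(nchar(out) < 1L)[1L]])
  }
  out
}

#' Write a FASTA file (wrapped at 60 columns)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(names(seqs)) == length(seqs))
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + 59L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Reverse complement of a DNA/RNA string
#' @param seq Character scalar over A,C,G,T,U,N.
#' @return Reverse-complemented string (same alphabet; U maps to A).
#' @export
revcomp <- function(seq) {
  chartr("ACGTUN", "TGCAAN",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

#' Convert a DNA string to its RNA view (T -> U)
#' @param seq Character vector.
#' @return Character vector with T replaced by U.
#' @export
dna_to_rna <- function(seq) chartr("Tt", "Uu", seq)

# ---------------------------------------------------------- transcript model

#' Construct a transcript model
#'
#' The unit flowing through every stage: a stranded, exon-structured
#' transcript on a named sequence, with optional CDS.
#'
#' @param transcript_id,gene_id,seq_name Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of 0-based half-open `[start, end)`
#'   intervals, non-overlapping; stored sorted ascending by start.
#' @param cds Optional two-column matrix of CDS intervals, each contained in
#'   some exon.
#' @param biotype One of `"coding"`, `"assembled"`, `"lncRNA_candidate"`.
#' @param source,attributes GTF bookkeeping carried through read/write.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, seq_name, strand, exons,
                             cds = NULL, biotype = "assembled",
                             source = "thermolnc", attributes = "") {
  if (!strand %in% c("+", "-")) .tl_fail("transcript %s: bad strand", transcript_id)
  exons <- matrix(as.numeric(exons), ncol = 2L)
  if (nrow(exons) == 0L) .tl_fail("transcript %s: no exons", transcript_id)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L])) {
    .tl_fail("transcript %s: zero-length exon", transcript_id)
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    .tl_fail("transcript %s: overlapping exons", transcript_id)
  }
  if (!is.null(cds)) {
    cds <- matrix(as.numeric(cds), ncol = 2L)
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
    }, TRUE)
    if (!all(inside)) .tl_fail("transcript %s: CDS outside exons", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 seq_name = seq_name, strand = strand, exons = exons,
                 cds = cds, biotype = biotype, source = source,
                 attributes = attributes),
            class = "transcript_model")
}

#' Spliced (mature) length of a transcript model in nucleotides
#' @param model A `transcript_model`.
#' @return Integer length.
#' @export
spliced_length <- function(model) sum(model$exons[, 2L] - model$exons[, 1L])

#' Genomic span of a transcript model
#' @param model A `transcript_model`.
#' @return Numeric `[start, end)` of the full genomic footprint.
#' @export
transcript_span <- function(model) {
  c(model$exons[1L, 1L], model$exons[nrow(model$exons), 2L])
}

#' Extract the spliced sense sequence of a transcript
#'
#' Exons are concatenated in genomic order and reverse-complemented for
#' minus-strand models.
#'
#' @param model A `transcript_model`.
#' @param genome Named character vector (as from [read_fasta()]).
#' @param rna If `TRUE`, return the RNA view (U instead of T).
#' @return Character scalar.
#' @export
spliced_sequence <- function(model, genome, rna = FALSE) {
  chrom <- genome[[model$seq_name]]
  if (is.null(chrom)) .tl_fail("sequence %s not in genome", model$seq_name)
  s <- paste(substring(chrom, model$exons[, 1L] + 1L, model$exons[, 2L]),
             collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  if (rna) dna_to_rna(s) else s
}

# ----------------------------------------------------------------------- GTF

.parse_gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(sprintf('%s "[^"]*"', key), attr))
  if (length(m) == 0L) NA_character_ else sub(sprintf('%s "([^"]*)"', key), "\\1", m)
}

#' Read transcript models from a GTF file
#'
#' GTF 2.2 dialect: tab-separated, 1-based inclusive coordinates, attributes
#' of the form `key "value";`.  Only `exon` and `CDS` features are used; exon
#' rows are grouped by `transcript_id` and converted to internal 0-based
#' half-open intervals.
#'
#' @param path Path to a GTF file.
#' @param coding_only Keep only transcripts that have CDS features.
#' @return List of [transcript_model()] objects in order of first appearance.
#' @export
read_gtf <- function(path, coding_only = FALSE) {
  if (!file.exists(path)) .tl_fail("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) .tl_fail("line %d: expected 9 tab-separated GTF fields",
                             line_no[which(nf < 9L)[1L]])
  feat <- vapply(fields, `[[`, "", 3L)
  use <- feat %in% c("exon", "CDS")
  fields <- fields[use]; feat <- feat[use]; line_no <- line_no[use]
  if (length(fields) == 0L) .tl_fail("no exon/CDS rows in %s", path)
  seqn <- vapply(fields, `[[`, "", 1L)
  src <- vapply(fields, `[[`, "", 2L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 7L)
  attr <- vapply(fields, `[[`, "", 9L)
  if (anyNA(start) || anyNA(end)) {
    .tl_fail("line %d: non-numeric coordinate",
             line_no[which(is.na(start) | is.na(end))[1L]])
  }
  if (any(end < start)) .tl_fail("line %d: zero-length feature (end < start)",
                                 line_no[which(end < start)[1L]])
  tid <- vapply(attr, .parse_gtf_attr, "", key = "transcript_id", USE.NAMES = FALSE)
  gid <- vapply(attr, .parse_gtf_attr, "", key = "gene_id", USE.NAMES = FALSE)
  if (anyNA(tid)) .tl_fail("line %d: missing transcript_id attribute",
                           line_no[which(is.na(tid))[1L]])
  if (anyNA(gid)) .tl_fail("line %d: missing gene_id attribute",
                           line_no[which(is.na(gid))[1L]])
  extra <- gsub('\\s*(gene_id|transcript_id) "[^"]*";?', "", attr)
  extra <- trimws(extra)

  models <- list()
  for (id in unique(tid)) {
    rows <- which(tid == id)
    ex <- rows[feat[rows] == "exon"]
    cd <- rows[feat[rows] == "CDS"]
    if (length(ex) == 0L) .tl_fail("transcript %s has no exon rows", id)
    if (length(unique(strand[rows])) != 1L) .tl_fail("transcript %s: mixed strand", id)
    if (length(unique(seqn[rows])) != 1L) .tl_fail("transcript %s: mixed seq_name", id)
    models[[id]] <- transcript_model(
      transcript_id = id, gene_id = gid[rows[1L]], seq_name = seqn[rows[1L]],
      strand = strand[rows[1L]],
      exons = cbind(start[ex] - 1, end[ex]),
      cds = if (length(cd)) cbind(start[cd] - 1, end[cd]) else NULL,
      biotype = if (length(cd)) "coding" else "assembled",
      source = src[rows[1L]], attributes = extra[rows[1L]])
  }
  if (coding_only) models <- Filter(function(m) !is.null(m$cds), models)
  unname(models)
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()] on canonicalised files: internal `[s, e)` becomes
#' GTF `[s + 1, e]`, unknown attributes are preserved verbatim.
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- character(0)
  for (m in models) {
    base_attr <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id,
                         m$transcript_id)
    a <- if (nzchar(m$attributes)) paste(base_attr, m$attributes) else base_attr
    fmt <- function(feature, iv) {
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", m$seq_name, m$source, feature,
              as.integer(iv[, 1L] + 1), as.integer(iv[, 2L]), m$strand, a)
    }
    rows <- c(rows, fmt("exon", m$exons),
              if (!is.null(m$cds)) fmt("CDS", m$cds))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------- TSV tables

.read_tsv <- function(path, required) {
  if (!file.exists(path)) .tl_fail("file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) .tl_fail("%s: missing column(s): %s", path,
                                paste(missing, collapse = ", "))
  df
}

.as_num <- function(x, path, col) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) && !all(is.na(x) == is.na(v))) {
    .tl_fail("%s: non-numeric value in column '%s'", path, col)
  }
  if (anyNA(v)) .tl_fail("%s: non-numeric value in column '%s'", path, col)
  v
}

#' Read a transcript-by-sample fragment count table
#'
#' Tab-separated with a header; first column `transcript_id`, remaining
#' columns one per sample.  Counts must be non-negative integers.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, rownames = transcript ids, colnames = sample ids.
#' @export
read_counts_table <- function(path) {
  df <- .read_tsv(path, "transcript_id")
  samples <- setdiff(names(df), "transcript_id")
  if (length(samples) == 0L) .tl_fail("%s: no sample columns", path)
  m <- sapply(samples, function(s) .as_num(df[[s]], path, s))
  m <- matrix(m, ncol = length(samples),
              dimnames = list(df$transcript_id, samples))
  if (any(m < 0)) .tl_fail("%s: negative count", path)
  if (any(m != round(m))) .tl_fail("%s: non-integer count", path)
  storage.mode(m) <- "integer"
  m
}

#' Read a sample sheet (sample_id, condition, library_size)
#' @param path Path to the TSV.
#' @return data.frame with those three columns.
#' @export
read_samples_table <- function(path) {
  df <- .read_tsv(path, c("sample_id", "condition", "library_size"))
  df$library_size <- .as_num(df$library_size, path, "library_size")
  if (any(df$library_size <= 0)) .tl_fail("%s: non-positive library_size", path)
  df
}

#' Read an external coding-potential score table
#'
#' Columns: `transcript_id`, `cpc`, `txcds`, `cnci` (numeric).
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_scores_table <- function(path) {
  df <- .read_tsv(path, c("transcript_id", "cpc", "txcds", "cnci"))
  for (col in c("cpc", "txcds", "cnci")) df[[col]] <- .as_num(df[[col]], path, col)
  df
}

#' Read a protein-domain hit table
#'
#' Columns: `transcript_id`, `hit` (0/1).  A transcript with any `hit = 1` row
#' is treated as domain-positive.
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_domain_hits <- function(path) {
  df <- .read_tsv(path, c("transcript_id", "hit"))
  df$hit <- .as_num(df$hit, path, "hit") != 0
  df
}

#' Read a gene-to-pathway membership map
#'
#' Columns: `gene_id`, `pathway_id`, `pathway_name`.
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_pathway_map <- function(path) {
  .read_tsv(path, c("gene_id", "pathway_id", "pathway_name"))
}

#' Write a data frame as a plain TSV (UTF-8, Unix newlines)
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

# ------------------------------------------------------- expression matrix

#' Construct an expression matrix
#'
#' Per-transcript fragment counts across named samples grouped into two
#' conditions, with per-sample total mapped fragments (library sizes) and the
#' spliced transcript lengths needed for FPKM.
#'
#' @param counts Non-negative integer matrix (transcripts x samples).
#' @param condition Character vector (one per sample) with two levels, e.g.
#'   `"control"` / `"heat"`.
#' @param library_size Per-sample positive totals; must be >= the column sums
#'   of `counts`. Defaults to the column sums.
#' @param lengths Named numeric vector of spliced lengths (nt) covering all
#'   transcripts; optional until FPKM is needed.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, condition, library_size = NULL,
                              lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    .tl_fail("counts must have transcript rownames and sample colnames")
  }
  if (any(counts < 0)) .tl_fail("negative count")
  if (length(condition) != ncol(counts)) .tl_fail("condition length != n samples")
  if (length(unique(condition)) < 1L || any(table(condition) < 1L)) {
    .tl_fail("each condition needs >= 1 sample")
  }
  if (is.null(library_size)) library_size <- colSums(counts)
  if (length(library_size) != ncol(counts) || any(library_size <= 0)) {
    .tl_fail("library_size must be positive, one per sample")
  }
  if (any(library_size < colSums(counts))) {
    .tl_fail("library_size below column sum of counts")
  }
  if (!is.null(lengths)) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing)) .tl_fail("lengths missing for %d transcripts (e.g. %s)",
                                  length(missing), missing[1L])
    lengths <- lengths[rownames(counts)]
  }
  structure(list(counts = counts,
                 transcript_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 condition = setNames(as.character(condition), colnames(counts)),
                 library_size = setNames(as.numeric(library_size), colnames(counts)),
                 lengths = lengths),
            class = "expression_matrix")
}
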