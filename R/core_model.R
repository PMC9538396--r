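#' @title Core domain types and file readers
#' @description Gene annotations, homolog pairs and codon alignments shared by
#'   every stage of the pipeline, plus readers/writers for the standard file
#'   formats those objects travel in (GFF3 / ordered gene TSV, BLAST tabular
#'   outfmt-6, pairwise FASTA).
#' @name core_model
NULL

# ---------------------------------------------------------------------------
# GenomeAnnotation
# ---------------------------------------------------------------------------

#' Construct a genome annotation
#'
#' A genome annotation is an ordered gene table for one genome. Genes are
#' sorted by start coordinate within each chromosome and assigned a 0-based
#' `order_index` (rank along the chromosome). All downstream block and window
#' arithmetic operates on `order_index`; base-pair coordinates are kept only
#' for breakpoint reporting.
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end` and optionally `strand` (defaults to `"+"`).
#' @param genome_id single string naming the genome.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genome_id` and `genes` (the sorted table with `order_index` added).
#' @export
genome_annotation <- function(genes, genome_id) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  required <- c("gene_id", "chromosome", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes <- data.frame(
    gene_id = as.character(genes$gene_id),
    chromosome = as.character(genes$chromosome),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand),
    stringsAsFactors = FALSE
  )
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id in genome '", genome_id, "': ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start]
    stop("end < start for gene(s): ", paste(bad, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  # sort by chromosome, then start; ties on start broken by gene_id so the
  # ordering (and therefore every order_index) is deterministic
  ord <- order(genes$chromosome, genes$start, genes$gene_id, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  genes$order_index <- stats::ave(
    seq_len(nrow(genes)), genes$chromosome,
    FUN = function(i) seq_along(i) - 1L
  )
  genes$order_index <- as.integer(genes$order_index)
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes on %d chromosome(s)\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$chromosome))))
  invisible(x)
}

#' Read a gene annotation from GFF3 or a 4/5-column TSV
#'
#' Accepts either GFF3 (rows with `type == "gene"`; the `ID` attribute is the
#' gene identifier) or a tab-separated table with columns chromosome,
#' gene_id, start, end and optionally strand (a leading `#` header line is
#' allowed). Unsorted input is sorted, not rejected; duplicate gene
#' identifiers are an error.
#'
#' @param path file path.
#' @param genome_id genome name for the resulting annotation.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A [genome_annotation()].
#' @export
read_gene_annotation <- function(path, genome_id,
                                 format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (length(gr) == 0) stop("no 'gene' features in ", path)
    genes <- data.frame(
      gene_id = as.character(gr$ID),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("TSV annotation needs >= 4 columns, got ", ncol(tab))
    genes <- data.frame(
      chromosome = as.character(tab[[1]]),
      gene_id = as.character(tab[[2]]),
      start = as.integer(tab[[3]]),
      end = as.integer(tab[[4]]),
      stringsAsFactors = FALSE
    )
    genes$strand <- if (ncol(tab) >= 5) as.character(tab[[5]]) else "+"
  }
  genome_annotation(genes, genome_id)
}

#' Write a gene annotation as an ordered 5-column TSV
#'
#' Emits the reader-compatible tab-separated layout (chromosome, gene_id,
#' start, end, strand) with a `#`-prefixed header line.
#'
#' @param ann a [genome_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#chromosome\tgene_id\tstart\tend\tstrand", con)
  utils::write.table(
    ann$genes[, c("chromosome", "gene_id", "start", "end", "strand")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# fast gene_id -> (chromosome, order_index, start, end, strand) lookup
.ann_lookup <- function(ann) {
  g <- ann$genes
  idx <- seq_len(nrow(g))
  names(idx) <- g$gene_id
  list(genes = g, idx = idx, genome_id = ann$genome_id)
}

# ---------------------------------------------------------------------------
# HomologPair
# ---------------------------------------------------------------------------

#' Filter and canonicalize homolog pairs
#'
#' Applies the homology significance thresholds (E-value < `e_max`, bit score
#' > `score_min`), removes self-hits, and collapses reciprocal duplicates to
#' one canonical row keeping the best bit score. Within-genome pairs are
#' canonicalized so `gene_a < gene_b`; cross-genome pairs keep the query
#' genome first. The operation is idempotent.
#'
#' @param pairs data.frame with columns `genome_a`, `gene_a`, `genome_b`,
#'   `gene_b`, `e_value`, `bit_score`.
#' @param e_max,score_min significance thresholds.
#' @return The filtered pair table.
#' @export
filter_homolog_pairs <- function(pairs, e_max = 1e-5, score_min = 100) {
  need <- c("genome_a", "gene_a", "genome_b", "gene_b", "e_value", "bit_score")
  stopifnot(all(need %in% names(pairs)))
  keep <- pairs$e_value < e_max & pairs$bit_score > score_min
  pairs <- pairs[keep, , drop = FALSE]
  # drop self-hits
  pairs <- pairs[!(pairs$genome_a == pairs$genome_b &
                     pairs$gene_a == pairs$gene_b), , drop = FALSE]
  if (nrow(pairs) == 0) {
    rownames(pairs) <- NULL
    return(pairs)
  }
  within <- pairs$genome_a == pairs$genome_b
  flip <- within & pairs$gene_a > pairs$gene_b
  if (any(flip)) {
    tmp <- pairs$gene_a[flip]
    pairs$gene_a[flip] <- pairs$gene_b[flip]
    pairs$gene_b[flip] <- tmp
  }
  key <- paste(pairs$genome_a, pairs$gene_a, pairs$genome_b, pairs$gene_b,
               sep = "\r")
  ord <- order(key, -pairs$bit_score, pairs$e_value, method = "radix")
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(paste(pairs$genome_a, pairs$gene_a,
                                   pairs$genome_b, pairs$gene_b, sep = "\r")),
                 , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Read a BLAST tabular (outfmt 6) homolog table
#'
#' Parses the 12-column tabular dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), applies the significance
#' thresholds, and canonicalizes reciprocal duplicates via
#' [filter_homolog_pairs()]. Malformed rows are skipped with one warning
#' reporting the count.
#'
#' @param path path to the tabular file.
#' @param genome_q,genome_s genome identifiers of query and subject.
#' @inheritParams filter_homolog_pairs
#' @return data.frame of canonical homolog pairs.
#' @export
read_homolog_table <- function(path, genome_q, genome_s,
                               e_max = 1e-5, score_min = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(filter_homolog_pairs(data.frame(
      genome_a = character(), gene_a = character(),
      genome_b = character(), gene_b = character(),
      e_value = numeric(), bit_score = numeric(),
      stringsAsFactors = FALSE
    ), e_max, score_min))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= 12
  evalue <- suppressWarnings(vapply(fields, function(f)
    if (length(f) >= 12) as.numeric(f[11]) else NA_real_, numeric(1)))
  bitscore <- suppressWarnings(vapply(fields, function(f)
    if (length(f) >= 12) as.numeric(f[12]) else NA_real_, numeric(1)))
  ok <- ok & !is.na(evalue) & !is.na(bitscore)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("skipped %d malformed row(s) in %s", n_bad, path))
  }
  fields <- fields[ok]
  pairs <- data.frame(
    genome_a = genome_q,
    gene_a = vapply(fields, `[[`, character(1), 1L),
    genome_b = genome_s,
    gene_b = vapply(fields, `[[`, character(1), 2L),
    e_value = evalue[ok],
    bit_score = bitscore[ok],
    stringsAsFactors = FALSE
  )
  filter_homolog_pairs(pairs, e_max = e_max, score_min = score_min)
}

#' Write homolog pairs as a BLAST-style tabular file
#'
#' Emits 12 tab-separated columns compatible with [read_homolog_table()]
#' (unknown alignment statistics are written as zeros).
#'
#' @param pairs canonical pair table.
#' @param path output path.
#' @export
write_homolog_table <- function(pairs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(pairs) > 0) {
    out <- sprintf("%s\t%s\t0\t0\t0\t0\t0\t0\t0\t0\t%g\t%g",
                   pairs$gene_a, pairs$gene_b, pairs$e_value, pairs$bit_score)
    writeLines(out, con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# CodonAlignment
# ---------------------------------------------------------------------------

#' Construct a codon alignment
#'
#' A pair of gap-aligned coding sequences over `{A,C,G,T,-}`. Sequences must
#' have equal length, a multiple of 3, with gaps in frame (every codon is
#' either three bases or contains at least one `-`; frame is never shifted).
#'
#' @param seq_a,seq_b aligned CDS strings.
#' @param pair_id identifier for the pair.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seq_a, seq_b, pair_id = "pair") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("alignment '", pair_id, "': sequence lengths differ (",
         nchar(seq_a), " vs ", nchar(seq_b), ")")
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("alignment '", pair_id, "': length ", nchar(seq_a),
         " is not a multiple of 3")
  }
  structure(list(pair_id = pair_id, seq_a = seq_a, seq_b = seq_b),
            class = "codon_alignment")
}

#' Read pairwise codon alignments from FASTA
#'
#' Consecutive records are paired: records 1+2 form the first alignment,
#' 3+4 the second, and so on. An odd record count, unequal lengths within a
#' pair, or a length not divisible by 3 is an error naming the records.
#'
#' @param path FASTA file of gap-aligned CDS.
#' @return list of [codon_alignment()] objects.
#' @export
read_codon_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) %% 2 != 0) {
    stop("odd number of FASTA records (", length(seqs),
         ") in ", path, "; records pair consecutively")
  }
  out <- vector("list", length(seqs) %/% 2)
  for (i in seq_along(out)) {
    a <- 2L * i - 1L; b <- 2L * i
    id_a <- names(seqs)[a]; id_b <- names(seqs)[b]
    out[[i]] <- tryCatch(
      codon_alignment(as.character(seqs[[a]]), as.character(seqs[[b]]),
                      pair_id = paste(id_a, id_b, sep = "|")),
      error = function(e) stop("records '", id_a, "' / '", id_b, "': ",
                               conditionMessage(e))
    )
  }
  out
}

#' Write pairwise codon alignments to FASTA
#'
#' @param alignments list of [codon_alignment()] objects.
#' @param path output FASTA path.
#' @export
write_codon_alignments <- function(alignments, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (al in alignments) {
    ids <- strsplit(al$pair_id, "|", fixed = TRUE)[[1]]
    if (length(ids) != 2) ids <- paste0(al$pair_id, c("_a", "_b"))
    writeLines(c(paste0(">", ids[1]), al$seq_a,
                 paste0(">", ids[2]), al$seq_b), con)
  }
  invisible(path)
}
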