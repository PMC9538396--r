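#' @title Event-related multi-genome alignment table
#' @description A hierarchical homolog matrix in reference gene order: one
#'   column group per reference (ECH) copy, each group holding one reference
#'   column plus three slot columns per hexaploid genome (one per subgenome
#'   copy). Missing homologs -- lost or translocated genes -- are dot-filled.
#'   With two hexaploid genomes and a triplicated reference this is the
#'   (1 + 3 + 3) x 3 = 21-column layout.
#' @name alignment_table
NULL

#' Assign orthologous regions to subgenome slots
#'
#' For each target genome and each reference chromosome, orthologous blocks
#' are ranked by anchor count and packed greedily into `n_slots` slots such
#' that blocks sharing a slot do not overlap on the reference axis (beyond
#' `overlap_tol` genes). A translocated subgenome therefore keeps a single
#' slot: its pieces occupy disjoint reference intervals. Regions beyond
#' `n_slots` overlapping candidates are dropped and logged. Each reference
#' gene's ortholog (its anchor partner) is then placed in its block's slot.
#'
#' @param blocks a classified `synteny_blocks` object (reference genome must
#'   be `genome_a`).
#' @param ref_ann reference [genome_annotation()].
#' @param events block labels treated as orthologous; `NULL` keeps all.
#' @param n_slots slots per genome (3 for a hexaploid).
#' @param overlap_tol permitted reference-overlap (genes) within a slot.
#' @return object of class `slot_map`: list with `map` (ref_gene, genome,
#'   slot, target_gene, block_id), `block_slots` (block_id, genome, slot),
#'   and `dropped` (block ids not placed).
#' @export
assign_slots <- function(blocks, ref_ann, events = "divergence",
                         n_slots = 3, overlap_tol = 2) {
  b <- blocks$blocks
  if (!is.null(events)) b <- b[b$event_label %in% events, , drop = FALSE]
  b <- b[b$genome_a == ref_ann$genome_id, , drop = FALSE]
  an <- blocks$anchors[blocks$anchors$block_id %in% b$block_id, , drop = FALSE]
  span <- do.call(rbind, lapply(split(an, an$block_id), function(a) {
    data.frame(block_id = a$block_id[1], lo = min(a$order_a),
               hi = max(a$order_a), stringsAsFactors = FALSE)
  }))
  b <- merge(b, span, by = "block_id")
  block_slots <- list(); dropped <- character()
  for (g in unique(b$genome_b)) {
    for (chr in unique(b$chromosome_a[b$genome_b == g])) {
      sel <- b[b$genome_b == g & b$chromosome_a == chr, , drop = FALSE]
      sel <- sel[order(-sel$n_anchors, sel$block_id), , drop = FALSE]
      slots <- replicate(n_slots, NULL, simplify = FALSE)
      for (i in seq_len(nrow(sel))) {
        # feasible slots: no reference-interval overlap with what they hold;
        # among those, prefer the slot already aligning to the same target
        # chromosome (pieces of one subgenome usually share chromosomes)
        feasible <- integer(0); affinity <- integer(0)
        for (s in seq_len(n_slots)) {
          occupied <- slots[[s]]
          clash <- FALSE
          if (!is.null(occupied)) {
            ov <- pmin(occupied$hi, sel$hi[i]) - pmax(occupied$lo, sel$lo[i]) + 1
            clash <- any(ov > overlap_tol)
          }
          if (!clash) {
            feasible <- c(feasible, s)
            affinity <- c(affinity,
                          if (is.null(occupied)) 0L else
                            sum(occupied$chromosome_b == sel$chromosome_b[i]))
          }
        }
        if (length(feasible) > 0) {
          s <- feasible[which.max(affinity)]
          slots[[s]] <- rbind(slots[[s]],
                              sel[i, c("block_id", "lo", "hi",
                                       "chromosome_b"), drop = FALSE])
          block_slots[[length(block_slots) + 1L]] <- data.frame(
            block_id = sel$block_id[i], genome = g, slot = s,
            stringsAsFactors = FALSE)
        } else {
          dropped <- c(dropped, sel$block_id[i])
        }
      }
    }
  }
  block_slots <- if (length(block_slots) > 0) do.call(rbind, block_slots) else
    data.frame(block_id = character(), genome = character(), slot = integer(),
               stringsAsFactors = FALSE)
  if (length(dropped) > 0) {
    message("assign_slots: ", length(dropped),
            " block(s) exceeded available slots and were dropped")
  }
  # place anchors
  an2 <- merge(an, block_slots, by = "block_id")
  if (nrow(an2) > 0) {
    bmeta <- b[, c("block_id", "n_anchors")]
    an2 <- merge(an2, bmeta, by = "block_id")
    # one cell per (ref gene, genome, slot): prefer the larger block
    ord <- order(an2$gene_a, an2$genome, an2$slot, -an2$n_anchors,
                 an2$block_id, method = "radix")
    an2 <- an2[ord, , drop = FALSE]
    an2 <- an2[!duplicated(paste(an2$gene_a, an2$genome, an2$slot,
                                 sep = "\r")), , drop = FALSE]
    # a target gene may occupy at most one cell
    ord <- order(an2$gene_b, -an2$n_anchors, an2$block_id, method = "radix")
    an2 <- an2[ord, , drop = FALSE]
    an2 <- an2[!duplicated(an2$gene_b), , drop = FALSE]
  }
  map <- data.frame(ref_gene = an2$gene_a, genome = an2$genome,
                    slot = an2$slot, target_gene = an2$gene_b,
                    block_id = an2$block_id, stringsAsFactors = FALSE)
  structure(list(map = map, block_slots = block_slots,
                 dropped = unique(dropped)),
            class = "slot_map")
}

#' Build the event-related multi-genome alignment table
#'
#' Rows are the reference genes in reference gene order. Each column group
#' corresponds to one reference (ECH) copy and holds one reference column
#' followed by `n_slots` columns per target genome; a cell lacking a homolog
#' (gene loss or translocation) holds `"."`. Placing the same gene in two
#' cells is an error naming the gene.
#'
#' @param slot_maps a [assign_slots()] result, or a list of them (one per
#'   column group). Optionally each element carries a `ref_genes` named
#'   character vector giving that group's reference-column content keyed by
#'   row gene (default: the row genes themselves for the first group, dots
#'   for later groups).
#' @param ref_ann reference [genome_annotation()].
#' @param genomes character vector of target genome ids (column order).
#' @param n_slots slots per genome per group.
#' @return object of class `alignment_table`: list with `cells` (character
#'   data.frame), `row_info`, `col_info`, `ref_genome`, `genomes`,
#'   `n_slots`.
#' @export
build_table <- function(slot_maps, ref_ann, genomes, n_slots = 3) {
  if (inherits(slot_maps, "slot_map")) slot_maps <- list(slot_maps)
  n_groups <- length(slot_maps)
  rows <- ref_ann$genes
  n <- nrow(rows)
  cells <- list(); col_info <- list()
  for (g in seq_len(n_groups)) {
    sm <- slot_maps[[g]]
    ref_col <- if (!is.null(sm$ref_genes)) {
      v <- sm$ref_genes[rows$gene_id]
      ifelse(is.na(v), ".", v)
    } else if (g == 1) rows$gene_id else rep(".", n)
    nm <- sprintf("%s_g%d", ref_ann$genome_id, g)
    cells[[nm]] <- ref_col
    col_info[[length(col_info) + 1L]] <- data.frame(
      column = nm, group = g, genome = ref_ann$genome_id, slot = 0L,
      role = "reference", stringsAsFactors = FALSE)
    for (tg in genomes) {
      for (s in seq_len(n_slots)) {
        m <- sm$map[sm$map$genome == tg & sm$map$slot == s, , drop = FALSE]
        v <- stats::setNames(m$target_gene, m$ref_gene)[rows$gene_id]
        nm <- sprintf("%s_g%d_s%d", tg, g, s)
        cells[[nm]] <- ifelse(is.na(v), ".", unname(v))
        col_info[[length(col_info) + 1L]] <- data.frame(
          column = nm, group = g, genome = tg, slot = s,
          role = "target", stringsAsFactors = FALSE)
      }
    }
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE, optional = TRUE)
  names(cells) <- vapply(col_info, `[[`, character(1), "column")
  filled <- unlist(cells, use.names = FALSE)
  filled <- filled[filled != "."]
  if (anyDuplicated(filled)) {
    dup <- unique(filled[duplicated(filled)])
    stop("gene placed in more than one cell: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  structure(list(
    cells = cells,
    row_info = rows[, c("gene_id", "chromosome", "order_index")],
    col_info = do.call(rbind, col_info),
    ref_genome = ref_ann$genome_id,
    genomes = genomes,
    n_slots = n_slots
  ), class = "alignment_table")
}

#' @export
print.alignment_table <- function(x, ...) {
  cat(sprintf(
    "<alignment_table> %d rows x %d columns (ref %s; %d group(s); genomes: %s)\n",
    nrow(x$cells), ncol(x$cells), x$ref_genome,
    max(x$col_info$group), paste(x$genomes, collapse = ", ")))
  invisible(x)
}

#' Write an alignment table as TSV
#'
#' Header lines are `#`-prefixed: metadata lines then the column-name line.
#'
#' @param table an `alignment_table`.
#' @param path output path.
#' @export
write_alignment_table <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#ref_genome=", table$ref_genome),
    paste0("#genomes=", paste(table$genomes, collapse = ",")),
    paste0("#n_slots=", table$n_slots),
    paste0("#", paste(c("row_gene", "chromosome", "order_index",
                        names(table$cells)), collapse = "\t"))
  ), con)
  out <- cbind(table$row_info, table$cells)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an alignment table written by [write_alignment_table()]
#'
#' @param path input path.
#' @return an `alignment_table`.
#' @export
read_alignment_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "#")]
  meta <- function(k) sub(paste0("^#", k, "="), "",
                          hdr[startsWith(hdr, paste0("#", k, "="))][1])
  ref_genome <- meta("ref_genome")
  genomes <- strsplit(meta("genomes"), ",", fixed = TRUE)[[1]]
  n_slots <- as.integer(meta("n_slots"))
  col_line <- hdr[length(hdr)]
  col_names <- strsplit(sub("^#", "", col_line), "\t", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  mat <- do.call(rbind, fields)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- col_names
  row_info <- data.frame(gene_id = df$row_gene,
                         chromosome = df$chromosome,
                         order_index = as.integer(df$order_index),
                         stringsAsFactors = FALSE)
  cells <- df[, setdiff(col_names, c("row_gene", "chromosome", "order_index")),
              drop = FALSE]
  col_info <- do.call(rbind, lapply(names(cells), function(nm) {
    m <- regmatches(nm, regexec("^(.*)_g(\\d+)_s(\\d+)$", nm))[[1]]
    if (length(m) == 4) {
      data.frame(column = nm, group = as.integer(m[3]), genome = m[2],
                 slot = as.integer(m[4]), role = "target",
                 stringsAsFactors = FALSE)
    } else {
      m <- regmatches(nm, regexec("^(.*)_g(\\d+)$", nm))[[1]]
      data.frame(column = nm, group = as.integer(m[3]), genome = m[2],
                 slot = 0L, role = "reference", stringsAsFactors = FALSE)
    }
  }))
  structure(list(cells = cells, row_info = row_info, col_info = col_info,
                 ref_genome = ref_genome, genomes = genomes,
                 n_slots = n_slots), class = "alignment_table")
}

#' Count homolog pairs and genes attributed to an event
#'
#' Counts, over blocks carrying the given event label, the anchored homolog
#' pairs and the distinct genes involved.
#'
#' @param blocks a classified `synteny_blocks` object.
#' @param event event label.
#' @return list with `pairs` and `genes`.
#' @export
count_event_pairs <- function(blocks, event) {
  known <- union(c("ECH", "SCH", "CCH", "divergence", "outparalog",
                   "unassigned"),
                 unique(blocks$blocks$event_label))
  if (!event %in% known) stop("unknown event name: ", event)
  ids <- blocks$blocks$block_id[blocks$blocks$event_label == event]
  an <- blocks$anchors[blocks$anchors$block_id %in% ids, , drop = FALSE]
  list(pairs = nrow(an), genes = length(unique(c(an$gene_a, an$gene_b))))
}

#' Fraction of reference genes conserved in all three subgenome copies
#'
#' Numerator: (row, group) combinations where every slot of `genome` holds a
#' gene. Denominator: (row, group) combinations whose reference column holds
#' a gene (so only reference copies that exist are counted). Reported as a
#' percentage rounded to 2 decimals; numerator and denominator are exposed
#' so the statistic is auditable.
#'
#' @param table an `alignment_table`.
#' @param genome target genome id.
#' @return list with `percent`, `numerator`, `denominator`.
#' @export
conserved_triplet_fraction <- function(table, genome) {
  ci <- table$col_info
  if (nrow(table$cells) == 0) stop("empty alignment table")
  if (!genome %in% ci$genome[ci$role == "target"]) {
    stop("genome not in table: ", genome)
  }
  num <- 0L; den <- 0L
  for (g in sort(unique(ci$group))) {
    ref_col <- ci$column[ci$group == g & ci$role == "reference"]
    slot_cols <- ci$column[ci$group == g & ci$genome == genome &
                             ci$role == "target"]
    ref_present <- table$cells[[ref_col]] != "."
    den <- den + sum(ref_present)
    if (length(slot_cols) > 0) {
      full <- Reduce(`&`, lapply(slot_cols,
                                 function(cn) table$cells[[cn]] != "."))
      num <- num + sum(ref_present & full)
    }
  }
  if (den == 0) stop("no reference genes in table")
  list(percent = round(100 * num / den, 2), numerator = num,
       denominator = den)
}

#' Fraction of reference genes absent from all syntenic locations
#'
#' Over rows whose group-1 reference column holds a gene on the given
#' reference chromosome, the fraction where every slot cell of `genome`
#' (all groups) is a dot -- the gene has no surviving syntenic copy in that
#' genome.
#'
#' @param table an `alignment_table`.
#' @param genome target genome id.
#' @param chromosome reference chromosome; `NULL` for the whole genome.
#' @return list with `percent`, `absent`, `total`.
#' @export
absent_gene_fraction <- function(table, genome, chromosome = NULL) {
  ci <- table$col_info
  ref_col <- ci$column[ci$group == 1 & ci$role == "reference"]
  rows <- table$cells[[ref_col]] != "."
  if (!is.null(chromosome)) {
    rows <- rows & table$row_info$chromosome == chromosome
  }
  if (!any(rows)) stop("no reference genes selected")
  slot_cols <- ci$column[ci$genome == genome & ci$role == "target"]
  if (length(slot_cols) == 0) stop("genome not in table: ", genome)
  all_dot <- Reduce(`&`, lapply(slot_cols,
                                function(cn) table$cells[[cn]] == "."))
  absent <- sum(rows & all_dot)
  total <- sum(rows)
  list(percent = round(100 * absent / total, 2), absent = absent,
       total = total)
}
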