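#' @title Subgenome fractionation statistics
#' @description Post-polyploidy gene loss quantified per subgenome:
#'   LF/MF1/MF2 assignment by retained-gene counts, sliding-window retention
#'   profiles, retention-difference fractions, geometric modelling of
#'   loss-run lengths, breakpoint detection, and shared-breakpoint two-step
#'   duplication inference.
#' @name fractionation
NULL

# slot presence matrix for one genome+group: rows = reference genes (table
# order), columns = slots.
.slot_presence <- function(table, genome, group = 1) {
  ci <- table$col_info
  cols <- ci$column[ci$genome == genome & ci$group == group &
                      ci$role == "target"]
  if (length(cols) == 0) stop("genome/group not in table: ", genome)
  sapply(cols, function(cn) table$cells[[cn]] != ".")
}

#' Rank subgenome slots into LF / MF1 / MF2
#'
#' Per region (reference chromosome x column group), slots are ranked by
#' retained-gene count: most retained = LF (least fractionated), then MF1,
#' then MF2. Ties are broken deterministically by total anchor span (genes
#' between first and last retained position) and then slot index, and
#' flagged.
#'
#' @param table an `alignment_table`.
#' @param genome target genome id.
#' @return data.frame of class `subgenome_assignment`: chromosome, group,
#'   slot, retained, span, label, tie_flagged.
#' @export
assign_subgenomes <- function(table, genome) {
  ci <- table$col_info
  groups <- sort(unique(ci$group[ci$genome == genome & ci$role == "target"]))
  out <- list()
  labels_all <- c("LF", "MF1", "MF2")
  for (g in groups) {
    pres <- .slot_presence(table, genome, g)
    for (chr in unique(table$row_info$chromosome)) {
      sel <- table$row_info$chromosome == chr
      if (!any(sel)) next
      counts <- colSums(pres[sel, , drop = FALSE])
      spans <- apply(pres[sel, , drop = FALSE], 2, function(v) {
        w <- which(v)
        if (length(w) == 0) 0L else diff(range(w)) + 1L
      })
      nslot <- length(counts)
      ord <- order(-counts, -spans, seq_len(nslot))
      tie <- anyDuplicated(counts) > 0
      labels <- rep(NA_character_, nslot)
      labels[ord] <- labels_all[seq_len(nslot)]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr, group = g, slot = seq_len(nslot),
        retained = as.integer(counts), span = as.integer(spans),
        label = labels, tie_flagged = tie, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("subgenome_assignment", "data.frame")
  res
}

# label of each slot for one chromosome+group
.slot_labels <- function(assignment, chromosome, group = 1) {
  a <- assignment[assignment$chromosome == chromosome &
                    assignment$group == group, , drop = FALSE]
  stats::setNames(a$label, a$slot)
}

#' Sliding-window gene retention per subgenome
#'
#' Windows of `window_size` reference genes advanced by `step` along each
#' reference chromosome; per window and subgenome label, the fraction of
#' reference genes with a retained (non-dot) cell.
#'
#' @param table an `alignment_table`.
#' @param assignment an [assign_subgenomes()] result.
#' @param genome target genome id.
#' @param window_size,step window length and stride, in genes.
#' @param group column group.
#' @return data.frame of class `retention_profile`: chromosome, window_start
#'   (0-based order index), plus one rate column per subgenome label.
#' @export
retention_profile <- function(table, assignment, genome,
                              window_size = 20, step = 10, group = 1) {
  if (window_size < 1) stop("window_size must be >= 1")
  if (step < 1) stop("step must be >= 1")
  pres <- .slot_presence(table, genome, group)
  out <- list()
  for (chr in unique(table$row_info$chromosome)) {
    sel <- which(table$row_info$chromosome == chr)
    if (length(sel) == 0) next
    labels <- .slot_labels(assignment, chr, group)
    n <- length(sel)
    starts <- seq(1L, max(1L, n - window_size + 1L), by = step)
    for (st in starts) {
      idx <- sel[st:min(st + window_size - 1L, n)]
      rates <- colMeans(pres[idx, , drop = FALSE])
      row <- data.frame(chromosome = chr, window_start = st - 1L,
                        n_genes = length(idx), stringsAsFactors = FALSE)
      for (s in seq_along(rates)) {
        row[[labels[[as.character(s)]]]] <- rates[s]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("retention_profile", "data.frame")
  res
}

#' Fraction of windows whose retention rates differ by more than a threshold
#'
#' @param profile a [retention_profile()].
#' @param pair two subgenome labels, e.g. `c("LF", "MF2")`.
#' @param threshold retention-rate difference threshold.
#' @return fraction of windows with `|rate_a - rate_b| > threshold`.
#' @export
retention_difference_fraction <- function(profile, pair = c("LF", "MF1"),
                                          threshold = 0.05) {
  stopifnot(length(pair) == 2, all(pair %in% names(profile)))
  d <- abs(profile[[pair[1]]] - profile[[pair[2]]])
  mean(d > threshold)
}

#' Histogram of continuous gene-loss run lengths
#'
#' Maximal runs of consecutive dots in one subgenome's column, counted per
#' reference chromosome within the region the subgenome actually covers
#' (between its first and last retained gene), so unaligned chromosome ends
#' are not counted as giant losses and runs never span chromosome ends.
#'
#' @param table an `alignment_table`.
#' @param assignment an [assign_subgenomes()] result.
#' @param genome target genome id.
#' @param label subgenome label (`"LF"`, `"MF1"`, `"MF2"`), or `NULL` to
#'   pool all subgenomes.
#' @param group column group.
#' @return named integer vector: run length -> count (class
#'   `loss_run_histogram`).
#' @export
loss_run_histogram <- function(table, assignment, genome, label = NULL,
                               group = 1) {
  pres <- .slot_presence(table, genome, group)
  runs <- integer(0)
  for (chr in unique(table$row_info$chromosome)) {
    sel <- which(table$row_info$chromosome == chr)
    labels <- .slot_labels(assignment, chr, group)
    use_slots <- if (is.null(label)) seq_len(ncol(pres)) else
      as.integer(names(labels)[labels == label])
    for (s in use_slots) {
      v <- pres[sel, s]
      w <- which(v)
      if (length(w) < 2) next
      v <- v[w[1]:w[length(w)]]  # covered interior only
      r <- rle(!v)
      runs <- c(runs, r$lengths[r$values])
    }
  }
  if (length(runs) == 0) {
    out <- integer(0)
  } else {
    tab <- table(runs)
    out <- stats::setNames(as.integer(tab), names(tab))
  }
  class(out) <- c("loss_run_histogram", class(out))
  out
}

#' Fit a geometric distribution to loss-run lengths
#'
#' Fits the probability mass function `p * (1 - p)^(k - 1)` (support k >= 1)
#' to the observed normalized run-length frequencies by least squares over
#' the observed lengths; `p` is the "expansion parameter". The closed-form
#' maximum-likelihood estimate `1 / mean(k)` is reported alongside as a
#' cross-check, with the fit's R-squared and a regression F-test p-value
#' (fitted pmf versus the mean-only model).
#'
#' @param histogram a [loss_run_histogram()], a named count vector
#'   (length -> count), or a raw integer vector of run lengths.
#' @param min_lengths,min_runs data-sufficiency thresholds.
#' @return list of class `geometric_fit`: `p_hat`, `p_mle`, `r_squared`,
#'   `f_test_p`, `n_runs`.
#' @export
fit_geometric <- function(histogram, min_lengths = 5, min_runs = 100) {
  if (is.null(names(histogram))) {
    runs <- as.integer(histogram)
    tab <- table(runs)
    histogram <- stats::setNames(as.integer(tab), names(tab))
  }
  k <- as.integer(names(histogram))
  cnt <- as.numeric(histogram)
  stopifnot(all(k >= 1), all(cnt >= 0))
  n_runs <- sum(cnt)
  if (length(k) < min_lengths || n_runs < min_runs) {
    if (length(k) == 1 && k[1] == 1L && n_runs > 0) {
      # degenerate but well-defined: every run has length 1
      return(structure(list(p_hat = 1, p_mle = 1, r_squared = 1,
                            f_test_p = NA_real_, n_runs = n_runs),
                       class = "geometric_fit"))
    }
    stop("insufficient data: ", length(k), " distinct lengths, ",
         n_runs, " runs")
  }
  freq <- cnt / n_runs
  sse_fun <- function(p) sum((freq - p * (1 - p)^(k - 1))^2)
  opt <- stats::optimize(sse_fun, interval = c(1e-6, 1))
  p_hat <- opt$minimum
  sse <- opt$objective
  sst <- sum((freq - mean(freq))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  m <- length(k)
  f_p <- if (m > 2 && sse > 0) {
    f_stat <- ((sst - sse) / 1) / (sse / (m - 2))
    stats::pf(f_stat, 1, m - 2, lower.tail = FALSE)
  } else NA_real_
  structure(list(p_hat = p_hat,
                 p_mle = n_runs / sum(k * cnt),
                 r_squared = r2, f_test_p = f_p, n_runs = n_runs),
            class = "geometric_fit")
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf(
    "<geometric_fit> p_hat = %.4f (MLE %.4f), R^2 = %.4f, n = %d runs\n",
    x$p_hat, x$p_mle, x$r_squared, x$n_runs))
  invisible(x)
}

#' Detect subgenome breakpoints along the reference
#'
#' Orders each subgenome's blocks along the reference chromosome and reports
#' a breakpoint wherever consecutive blocks switch target chromosome
#' (translocation signature) or flip orientation (inversion signature).
#' Positions are the midpoint between the flanking anchors, in both order
#' index and base pairs.
#'
#' @param blocks a `synteny_blocks` object (reference = genome_a).
#' @param slot_map an [assign_slots()] result giving block -> slot.
#' @param assignment an [assign_subgenomes()] result labelling slots, or
#'   `NULL` to report raw slot numbers.
#' @param ref_ann reference [genome_annotation()].
#' @param genome target genome id, or `NULL` for all genomes in the map.
#' @return data.frame of class `breakpoint_set`: genome, subgenome,
#'   ref_chromosome, order_index, position_bp, type, from, to.
#' @export
detect_breakpoints <- function(blocks, slot_map, assignment = NULL, ref_ann,
                               genome = NULL) {
  bs <- slot_map$block_slots
  if (!is.null(genome)) bs <- bs[bs$genome == genome, , drop = FALSE]
  b <- merge(blocks$blocks, bs, by = "block_id")
  an <- blocks$anchors
  genes <- ref_ann$genes
  pos_of <- function(chr, ord) {
    hit <- genes[genes$chromosome == chr & genes$order_index == ord, ]
    if (nrow(hit) == 0) NA_real_ else (hit$start[1] + hit$end[1]) / 2
  }
  out <- list()
  for (g in unique(b$genome)) {
    for (s in unique(b$slot[b$genome == g])) {
      sel <- b[b$genome == g & b$slot == s, , drop = FALSE]
      for (chr in unique(sel$chromosome_a)) {
        bl <- sel[sel$chromosome_a == chr, , drop = FALSE]
        if (nrow(bl) < 2) next
        span <- do.call(rbind, lapply(bl$block_id, function(id) {
          a <- an[an$block_id == id, ]
          data.frame(block_id = id, lo = min(a$order_a), hi = max(a$order_a))
        }))
        bl <- merge(bl, span, by = "block_id")
        bl <- bl[order(bl$lo), , drop = FALSE]
        lab <- if (!is.null(assignment)) {
          labs <- .slot_labels(assignment, chr)
          unname(labs[as.character(s)])
        } else as.character(s)
        for (i in seq_len(nrow(bl) - 1L)) {
          chr_switch <- bl$chromosome_b[i] != bl$chromosome_b[i + 1L]
          ori_flip <- bl$orientation[i] != bl$orientation[i + 1L]
          if (!chr_switch && !ori_flip) next
          mid_ord <- floor((bl$hi[i] + bl$lo[i + 1L]) / 2)
          out[[length(out) + 1L]] <- data.frame(
            genome = g, subgenome = lab, ref_chromosome = chr,
            order_index = mid_ord,
            position_bp = pos_of(chr, mid_ord),
            type = if (chr_switch) "translocation" else "inversion",
            from = if (chr_switch) bl$chromosome_b[i] else bl$orientation[i],
            to = if (chr_switch) bl$chromosome_b[i + 1L] else
              bl$orientation[i + 1L],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else data.frame(
    genome = character(), subgenome = character(),
    ref_chromosome = character(), order_index = integer(),
    position_bp = numeric(), type = character(), from = character(),
    to = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("breakpoint_set", "data.frame")
  res
}

#' Group breakpoints shared between subgenomes and infer two-step duplication
#'
#' Breakpoints of different subgenomes on the same reference chromosome and
#' of the same type, within `tolerance_genes` of each other (order-index
#' distance), are grouped as shared. If at least one shared group is private
#' to exactly one subgenome pair, the verdict is that those two subgenomes
#' merged first (`"two-step (X,Y first)"`); groups spanning all subgenomes
#' are not private and carry no signal; otherwise `"inconclusive"`.
#'
#' @param breakpoints a [detect_breakpoints()] result (one genome).
#' @param tolerance_genes matching tolerance along the reference.
#' @return list with `shared` (data.frame: group, subgenomes, chromosome,
#'   type, order_index) and `verdict`.
#' @export
shared_breakpoints <- function(breakpoints, tolerance_genes = 10) {
  bp <- breakpoints
  if (nrow(bp) == 0) {
    return(list(shared = data.frame(), verdict = "inconclusive"))
  }
  bp$used <- FALSE
  groups <- list()
  ord <- order(bp$ref_chromosome, bp$type, bp$order_index)
  bp <- bp[ord, , drop = FALSE]
  for (i in seq_len(nrow(bp))) {
    if (bp$used[i]) next
    sel <- which(!bp$used &
                   bp$ref_chromosome == bp$ref_chromosome[i] &
                   bp$type == bp$type[i] &
                   abs(bp$order_index - bp$order_index[i]) <= tolerance_genes)
    bp$used[sel] <- TRUE
    subs <- sort(unique(bp$subgenome[sel]))
    groups[[length(groups) + 1L]] <- data.frame(
      group = length(groups) + 1L,
      subgenomes = paste(subs, collapse = "+"),
      n_subgenomes = length(subs),
      chromosome = bp$ref_chromosome[i], type = bp$type[i],
      order_index = round(mean(bp$order_index[sel])),
      stringsAsFactors = FALSE)
  }
  shared <- do.call(rbind, groups)
  pairs <- shared[shared$n_subgenomes == 2, , drop = FALSE]
  verdict <- "inconclusive"
  if (nrow(pairs) > 0) {
    tab <- sort(table(pairs$subgenomes), decreasing = TRUE)
    verdict <- sprintf("two-step (%s first)",
                       gsub("+", ",", names(tab)[1], fixed = TRUE))
  }
  list(shared = shared, verdict = verdict)
}
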