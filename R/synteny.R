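#' @title Collinear synteny-block detection
#' @description Chains homologous gene pairs into collinear blocks on gene
#'   order (dotplot diagonals), annotates blocks with median Ks, classifies
#'   them by evolutionary event, and infers orthologous depth ratios.
#' @name synteny
NULL

#' Remove pairs belonging to large gene families
#'
#' Homolog clusters are the connected components of the pair graph
#' (single-linkage). Any gene whose cluster reaches `max_family` members has
#' all of its pairs removed; large families produce dense off-diagonal hits
#' that swamp collinearity signal.
#'
#' @param pairs canonical homolog pair table.
#' @param max_family cluster size at or above which a family is dropped.
#' @return the filtered pair table.
#' @export
filter_large_families <- function(pairs, max_family = 50) {
  if (nrow(pairs) == 0) return(pairs)
  va <- paste(pairs$genome_a, pairs$gene_a, sep = "\r")
  vb <- paste(pairs$genome_b, pairs$gene_b, sep = "\r")
  g <- igraph::graph_from_data_frame(data.frame(va, vb), directed = FALSE)
  comp <- igraph::components(g)
  big <- which(comp$csize >= max_family)
  if (length(big) == 0) return(pairs)
  member_big <- names(comp$membership)[comp$membership %in% big]
  drop <- va %in% member_big | vb %in% member_big
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best chain (strictly increasing in both axes, gap constraint on both) among
# the anchors flagged active. Classic O(n^2) longest-chain DP; score = anchor
# count. Returns indices into oa/ob in chain order, or integer(0).
.best_chain <- function(oa, ob, active, max_gap) {
  idx <- which(active)
  if (length(idx) == 0) return(integer(0))
  a <- oa[idx]; b <- ob[idx]
  ord <- order(a, b, method = "radix")
  idx <- idx[ord]; a <- a[ord]; b <- b[ord]
  n <- length(idx)
  dp <- rep(1L, n)
  parent <- rep(0L, n)
  step <- max_gap + 1L  # <= max_gap intervening genes
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    ok <- a[j] < a[i] & b[j] < b[i] &
      (a[i] - a[j]) <= step & (b[i] - b[j]) <= step
    if (any(ok)) {
      cand <- j[ok]
      best <- cand[which.max(dp[cand])]
      dp[i] <- dp[best] + 1L
      parent[i] <- best
    }
  }
  end <- which.max(dp)
  chain <- integer(dp[end])
  k <- dp[end]; cur <- end
  while (cur != 0L) {
    chain[k] <- cur
    k <- k - 1L
    cur <- parent[cur]
  }
  idx[chain]
}

# Greedy non-overlapping chain extraction for one chromosome pair; both
# orientations are searched (antiparallel = chain on negated b-order), each
# extracted block has one orientation, anchors are consumed.
.extract_blocks_one <- function(oa, ob, max_gap, min_anchors) {
  active <- rep(TRUE, length(oa))
  out <- list()
  repeat {
    cp <- .best_chain(oa, ob, active, max_gap)
    cn <- .best_chain(oa, -ob, active, max_gap)
    if (length(cp) >= length(cn)) {  # tie broken toward parallel
      chain <- cp; orientation <- "parallel"
    } else {
      chain <- cn; orientation <- "antiparallel"
    }
    if (length(chain) < min_anchors) break
    out[[length(out) + 1L]] <- list(anchors = chain, orientation = orientation)
    active[chain] <- FALSE
  }
  out
}

#' Chain homolog pairs into collinear synteny blocks
#'
#' For every chromosome pair, anchors (pairs positioned by gene order on each
#' chromosome) are chained by longest-increasing / longest-decreasing dynamic
#' programming with a gap constraint of at most `max_gap` intervening genes
#' on both axes. Maximal chains are extracted greedily in decreasing anchor
#' count; anchors are consumed, so each belongs to at most one block. Chains
#' shorter than `min_anchors` are discarded.
#'
#' @param pairs canonical homolog pair table (one genome pair).
#' @param ann_a,ann_b [genome_annotation()] objects for the two genomes
#'   (pass the same object twice for a self-comparison).
#' @param max_gap maximum intervening genes between consecutive anchors.
#' @param min_anchors minimum syntenic gene pairs per block.
#' @return An object of class `synteny_blocks`: list with `blocks` (one row
#'   per block: block_id, genomes, chromosomes, n_anchors, orientation,
#'   median_ks, event_label) and `anchors` (block_id, gene_a, gene_b,
#'   order_a, order_b).
#' @export
chain_blocks <- function(pairs, ann_a, ann_b, max_gap = 50, min_anchors = 4) {
  empty <- structure(list(
    blocks = data.frame(block_id = character(), genome_a = character(),
                        genome_b = character(), chromosome_a = character(),
                        chromosome_b = character(), n_anchors = integer(),
                        orientation = character(), median_ks = numeric(),
                        event_label = character(), stringsAsFactors = FALSE),
    anchors = data.frame(block_id = character(), gene_a = character(),
                         gene_b = character(), order_a = integer(),
                         order_b = integer(), stringsAsFactors = FALSE)
  ), class = "synteny_blocks")
  if (nrow(pairs) == 0) return(empty)
  ga <- unique(pairs$genome_a); gb <- unique(pairs$genome_b)
  if (length(ga) != 1 || length(gb) != 1) {
    stop("chain_blocks expects pairs from a single genome pair")
  }
  if (ga != ann_a$genome_id || gb != ann_b$genome_id) {
    stop("annotations do not match the genomes in the pair table")
  }
  la <- .ann_lookup(ann_a); lb <- .ann_lookup(ann_b)
  ia <- la$idx[pairs$gene_a]; ib <- lb$idx[pairs$gene_b]
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)]))
    stop("pair gene(s) absent from annotation: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  chr_a <- la$genes$chromosome[ia]; chr_b <- lb$genes$chromosome[ib]
  oa <- la$genes$order_index[ia]; ob <- lb$genes$order_index[ib]
  self <- ga == gb & pairs$gene_a == pairs$gene_b
  keep <- !self
  key <- paste(chr_a, chr_b, sep = "\r")
  blocks <- list(); anchors <- list(); bi <- 0L
  for (k in sort(unique(key[keep]))) {
    sel <- which(keep & key == k)
    found <- .extract_blocks_one(oa[sel], ob[sel], max_gap, min_anchors)
    for (blk in found) {
      bi <- bi + 1L
      id <- sprintf("blk%05d", bi)
      rows <- sel[blk$anchors]
      blocks[[bi]] <- data.frame(
        block_id = id, genome_a = ga, genome_b = gb,
        chromosome_a = chr_a[rows[1]], chromosome_b = chr_b[rows[1]],
        n_anchors = length(rows), orientation = blk$orientation,
        median_ks = NA_real_, event_label = "unassigned",
        stringsAsFactors = FALSE
      )
      anchors[[bi]] <- data.frame(
        block_id = id, gene_a = pairs$gene_a[rows], gene_b = pairs$gene_b[rows],
        order_a = oa[rows], order_b = ob[rows], stringsAsFactors = FALSE
      )
    }
  }
  if (bi == 0L) return(empty)
  structure(list(blocks = do.call(rbind, blocks),
                 anchors = do.call(rbind, anchors)),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks> %d block(s), %d anchor pair(s)\n",
              nrow(x$blocks), nrow(x$anchors)))
  invisible(x)
}

#' Validate synteny-block invariants
#'
#' Checks, for every block: at least `min_anchors` anchors; `order_a`
#' strictly increasing; `order_b` strictly increasing (parallel) or strictly
#' decreasing (antiparallel); gaps of at most `max_gap` intervening genes on
#' both axes. Returns `TRUE` invisibly or stops with the offending block.
#'
#' @param blocks a `synteny_blocks` object.
#' @inheritParams chain_blocks
#' @export
validate_blocks <- function(blocks, max_gap = 50, min_anchors = 4) {
  for (id in blocks$blocks$block_id) {
    an <- blocks$anchors[blocks$anchors$block_id == id, , drop = FALSE]
    row <- blocks$blocks[blocks$blocks$block_id == id, ]
    if (nrow(an) < min_anchors) stop("block ", id, ": too few anchors")
    da <- diff(an$order_a); db <- diff(an$order_b)
    if (any(da <= 0)) stop("block ", id, ": order_a not strictly increasing")
    if (row$orientation == "parallel") {
      if (any(db <= 0)) stop("block ", id, ": order_b not increasing")
    } else {
      if (any(db >= 0)) stop("block ", id, ": order_b not decreasing")
    }
    if (any(da > max_gap + 1L) || any(abs(db) > max_gap + 1L)) {
      stop("block ", id, ": gap constraint violated")
    }
  }
  invisible(TRUE)
}

.pair_key <- function(genome_a, gene_a, genome_b, gene_b) {
  paste(genome_a, gene_a, genome_b, gene_b, sep = "\r")
}

#' Annotate blocks with their median Ks
#'
#' `median_ks` is the median over anchors with a defined Ks value; anchors
#' lacking Ks are ignored. A block with no defined Ks keeps `NA` and is
#' flagged in the returned object's `blocks$ks_flagged` column.
#'
#' @param blocks a `synteny_blocks` object.
#' @param ks_by_pair data.frame with columns `gene_a`, `gene_b`, `ks`
#'   (gene order within a row does not matter).
#' @return the blocks object with `median_ks` filled in.
#' @export
annotate_block_ks <- function(blocks, ks_by_pair) {
  stopifnot(all(c("gene_a", "gene_b", "ks") %in% names(ks_by_pair)))
  ks_map <- c(
    stats::setNames(ks_by_pair$ks,
                    paste(ks_by_pair$gene_a, ks_by_pair$gene_b, sep = "\r")),
    stats::setNames(ks_by_pair$ks,
                    paste(ks_by_pair$gene_b, ks_by_pair$gene_a, sep = "\r"))
  )
  anchor_ks <- ks_map[paste(blocks$anchors$gene_a, blocks$anchors$gene_b,
                            sep = "\r")]
  med <- tapply(anchor_ks, blocks$anchors$block_id,
                function(v) stats::median(v, na.rm = TRUE))
  m <- as.numeric(med[blocks$blocks$block_id])
  blocks$blocks$median_ks <- ifelse(is.nan(m), NA_real_, m)
  blocks$blocks$ks_flagged <- is.na(blocks$blocks$median_ks)
  blocks
}

#' Classify blocks by evolutionary event from Ks peaks
#'
#' Each block is labelled with the event whose peak mean is nearest to the
#' block's median Ks in units of that peak's standard deviation. For
#' cross-genome comparisons, blocks nearest the `divergence` peak are
#' orthologous (label `divergence`) and all others are labelled `outparalog`.
#' Exact ties are broken toward the smaller peak mean and flagged. Blocks
#' without a median Ks stay `unassigned`.
#'
#' @param blocks a `synteny_blocks` object with `median_ks` annotated.
#' @param event_peaks data.frame with columns `event`, `mu`, `sigma`.
#' @return the blocks object with `event_label` (and `tie_flagged`) filled.
#' @export
classify_block_event <- function(blocks, event_peaks) {
  stopifnot(all(c("event", "mu", "sigma") %in% names(event_peaks)))
  if (any(event_peaks$sigma <= 0)) stop("peak sigma must be > 0")
  b <- blocks$blocks
  cross <- b$genome_a != b$genome_b
  labels <- rep("unassigned", nrow(b))
  ties <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(b))) {
    m <- b$median_ks[i]
    if (is.na(m)) next
    d <- abs(m - event_peaks$mu) / event_peaks$sigma
    best <- min(d)
    cand <- which(d <= best + 1e-9)
    if (length(cand) > 1) {
      ties[i] <- TRUE
      cand <- cand[which.min(event_peaks$mu[cand])]
    }
    ev <- event_peaks$event[cand]
    if (cross[i]) {
      labels[i] <- if (ev == "divergence") "divergence" else "outparalog"
    } else {
      labels[i] <- ev
    }
  }
  blocks$blocks$event_label <- labels
  blocks$blocks$tie_flagged <- ties
  blocks
}

#' Infer the orthologous depth ratio between two genomes
#'
#' For each genome, the coverage depth of a gene is the number of distinct
#' orthologous blocks whose anchor span (on that genome's axis) covers the
#' gene's order index. The per-genome depth is the mode over genes with
#' coverage of at least 1. The ratio is reported as copies-in-A :
#' copies-in-B, i.e. `depth_a` is the modal number of blocks covering a gene
#' of genome B (how many times genome A's regions recur on B's regions) and
#' vice versa, together with the reduced (coprime) form.
#'
#' @param blocks a classified `synteny_blocks` object.
#' @param ann_a,ann_b the two annotations.
#' @param events block labels treated as orthologous.
#' @return list with `depth_a`, `depth_b`, `ratio` (string), `reduced`
#'   (string), and `coverage` (per-genome coverage tables).
#' @export
infer_depth_ratio <- function(blocks, ann_a, ann_b, events = "divergence") {
  sel <- blocks$blocks$event_label %in% events
  if (!any(sel)) stop("no orthologous blocks (labels: ",
                      paste(events, collapse = ", "), ")")
  ids <- blocks$blocks$block_id[sel]
  an <- blocks$anchors[blocks$anchors$block_id %in% ids, , drop = FALSE]
  meta <- blocks$blocks[sel, , drop = FALSE]
  cover_depth <- function(ann, chrom_col, ord_col) {
    genes <- ann$genes
    depth <- integer(nrow(genes))
    spans <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
      a <- an[an$block_id == meta$block_id[i], , drop = FALSE]
      data.frame(chromosome = meta[[chrom_col]][i],
                 lo = min(a[[ord_col]]), hi = max(a[[ord_col]]),
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(spans))) {
      hit <- genes$chromosome == spans$chromosome[i] &
        genes$order_index >= spans$lo[i] & genes$order_index <= spans$hi[i]
      depth[hit] <- depth[hit] + 1L
    }
    depth
  }
  depth_on_a <- cover_depth(ann_a, "chromosome_a", "order_a")
  depth_on_b <- cover_depth(ann_b, "chromosome_b", "order_b")
  modal <- function(d) {
    d <- d[d >= 1]
    if (length(d) == 0) return(0L)
    tab <- table(d)
    as.integer(names(tab)[which.max(tab)])
  }
  # copies-in-A = how deep genome A's regions pile on a genome-B gene
  depth_a <- modal(depth_on_b)
  depth_b <- modal(depth_on_a)
  g <- .gcd(depth_a, depth_b)
  list(
    depth_a = depth_a, depth_b = depth_b,
    ratio = paste(depth_a, depth_b, sep = ":"),
    reduced = if (g > 0) paste(depth_a %/% g, depth_b %/% g, sep = ":")
              else paste(depth_a, depth_b, sep = ":"),
    coverage = list(a = table(depth_on_a), b = table(depth_on_b))
  )
}

.gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
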