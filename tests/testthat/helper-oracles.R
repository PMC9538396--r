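# Independent oracles and fixture builders used across the suite.

# ---------------------------------------------------------------------------
# NG86 oracle: recursive pathway enumeration, written independently of the
# package's iterative/cached implementation. Conventions shared by contract:
# stop-codon changes are nonsynonymous for site counting; pathways through
# stops are excluded (all pathways used if every one is blocked); sites
# averaged over the two sequences; Jukes-Cantor correction.
# ---------------------------------------------------------------------------
oracle_gc <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
})

oracle_syn_sites <- function(cod) {
  aa <- oracle_gc[[cod]]
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(cod, pos, pos) == b) next
      alt <- cod
      substr(alt, pos, pos) <- b
      if (oracle_gc[[alt]] != "*" && oracle_gc[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

oracle_pathways <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(data.frame(sd = 0, nd = 0, blocked = FALSE))
  acc <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0) {
      acc[[length(acc) + 1]] <<- c(sd = sd, nd = nd, blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      syn <- oracle_gc[[cur]] != "*" && oracle_gc[[cur]] == oracle_gc[[nxt]]
      recurse(nxt, setdiff(remaining, p), sd + syn, nd + !syn,
              blocked || oracle_gc[[nxt]] == "*")
    }
  }
  recurse(c1, pos, 0, 0, FALSE)
  as.data.frame(do.call(rbind, acc))
}

oracle_ng86 <- function(seq_a, seq_b) {
  n_cod <- nchar(seq_a) %/% 3
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_len(n_cod)) {
    c1 <- substr(seq_a, 3 * i - 2, 3 * i)
    c2 <- substr(seq_b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (oracle_gc[[c1]] == "*" || oracle_gc[[c2]] == "*") next
    used <- used + 1
    S1 <- S1 + oracle_syn_sites(c1)
    S2 <- S2 + oracle_syn_sites(c2)
    pw <- oracle_pathways(c1, c2)
    open <- pw[!pw$blocked, , drop = FALSE]
    use <- if (nrow(open) > 0) open else pw
    Sd <- Sd + mean(use$sd)
    Nd <- Nd + mean(use$nd)
  }
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  jc <- function(p) if (4 / 3 * p >= 1) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ks = jc(if (S > 0) Sd / S else 0),
       ka = jc(if (N > 0) Nd / N else 0))
}

# random non-stop codon pairs for oracle comparisons
random_codon_seq <- function(n_codons) {
  codons <- names(oracle_gc)[oracle_gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# ---------------------------------------------------------------------------
# Chaining oracle: recursive memoized longest-chain search with the same
# deterministic tie-breaking contract as the package (anchors sorted by
# (order_a, order_b); among equal-length predecessor chains the earliest
# sorted anchor wins; ties between orientations go to parallel), plus its
# own greedy extraction loop. Independent of the vectorized implementation.
# ---------------------------------------------------------------------------
oracle_longest_chain <- function(oa, ob, active, max_gap) {
  idx <- which(active)
  if (length(idx) == 0) return(integer(0))
  ord <- order(oa[idx], ob[idx])
  idx <- idx[ord]
  a <- oa[idx]; b <- ob[idx]
  n <- length(idx)
  best_len <- rep(NA_integer_, n)
  best_prev <- rep(0L, n)
  step <- max_gap + 1L
  solve <- function(i) {
    if (!is.na(best_len[i])) return(best_len[i])
    len <- 1L; prev <- 0L
    if (i > 1) {
      for (j in 1:(i - 1)) {
        if (a[j] < a[i] && b[j] < b[i] &&
            (a[i] - a[j]) <= step && (b[i] - b[j]) <= step) {
          lj <- solve(j)
          if (lj + 1L > len) { len <- lj + 1L; prev <- j }
        }
      }
    }
    best_len[i] <<- len
    best_prev[i] <<- prev
    len
  }
  for (i in seq_len(n)) solve(i)
  end <- which.max(best_len)
  chain <- integer(best_len[end])
  k <- length(chain); cur <- end
  while (cur != 0L) { chain[k] <- cur; k <- k - 1L; cur <- best_prev[cur] }
  idx[chain]
}

oracle_extract_blocks <- function(oa, ob, max_gap, min_anchors) {
  active <- rep(TRUE, length(oa))
  out <- list()
  repeat {
    cp <- oracle_longest_chain(oa, ob, active, max_gap)
    cn <- oracle_longest_chain(oa, -ob, active, max_gap)
    if (length(cp) >= length(cn)) {
      chain <- cp; orientation <- "parallel"
    } else {
      chain <- cn; orientation <- "antiparallel"
    }
    if (length(chain) < min_anchors) break
    out[[length(out) + 1]] <- list(anchors = chain, orientation = orientation)
    active[chain] <- FALSE
  }
  out
}

# exhaustive maximum-chain length by subset enumeration (tiny n only)
oracle_exhaustive_max_chain <- function(oa, ob, max_gap) {
  n <- length(oa)
  stopifnot(n <= 14)
  step <- max_gap + 1L
  valid_chain <- function(sel, flip) {
    a <- oa[sel]; b <- if (flip) -ob[sel] else ob[sel]
    o <- order(a)
    a <- a[o]; b <- b[o]
    if (length(a) < 2) return(TRUE)
    all(diff(a) > 0) && all(diff(b) > 0) &&
      all(diff(a) <= step) && all(diff(b) <= step)
  }
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) <= best) next
    if (valid_chain(sel, FALSE) || valid_chain(sel, TRUE)) {
      best <- length(sel)
    }
  }
  best
}

# ---------------------------------------------------------------------------
# Fixture builders
# ---------------------------------------------------------------------------

# annotation with one chromosome of n uniformly spaced genes
toy_annotation <- function(genome_id, n, chrom = "c1", prefix = genome_id) {
  genome_annotation(data.frame(
    chromosome = chrom,
    gene_id = sprintf("%s_g%04d", prefix, seq_len(n)),
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 500L,
    strand = "+"), genome_id)
}

# homolog pair rows between two annotations by gene index
toy_pairs <- function(ann_a, ann_b, idx_a, idx_b,
                      e_value = 1e-50, bit_score = 200) {
  data.frame(genome_a = ann_a$genome_id,
             gene_a = ann_a$genes$gene_id[idx_a],
             genome_b = ann_b$genome_id,
             gene_b = ann_b$genes$gene_id[idx_b],
             e_value = e_value, bit_score = bit_score,
             stringsAsFactors = FALSE)
}

# alignment table with a given presence pattern: `presence` is a logical
# matrix (rows = reference genes, cols = slots) for one target genome
presence_table <- function(presence, genome = "Hex", ref_genome = "Ref",
                           chrom = "c1") {
  n <- nrow(presence)
  ref <- toy_annotation(ref_genome, n, chrom = chrom)
  rows <- which(presence, arr.ind = TRUE)
  map <- data.frame(
    ref_gene = ref$genes$gene_id[rows[, 1]],
    genome = genome,
    slot = as.integer(rows[, 2]),
    target_gene = sprintf("%s_s%d_%s", genome, rows[, 2],
                          ref$genes$gene_id[rows[, 1]]),
    block_id = NA_character_, stringsAsFactors = FALSE)
  sm <- structure(list(map = map, block_slots = data.frame(),
                       dropped = character()), class = "slot_map")
  build_table(sm, ref, genome)
}
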