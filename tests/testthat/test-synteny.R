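test_that("large families are removed by single-linkage cluster size", {
  # star family of exactly 50 members: all pairs removed
  hub <- data.frame(genome_a = "A", gene_a = "hub",
                    genome_b = "A", gene_b = sprintf("leaf%02d", 1:49),
                    e_value = 1e-50, bit_score = 200,
                    stringsAsFactors = FALSE)
  duo <- data.frame(genome_a = "A", gene_a = "x1", genome_b = "A",
                    gene_b = "x2", e_value = 1e-50, bit_score = 200,
                    stringsAsFactors = FALSE)
  out <- filter_large_families(rbind(hub, duo), max_family = 50)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_a, "x1")
  # a 49-member star (hub plus 48 leaves) survives
  hub48 <- hub[1:48, ]
  out49 <- filter_large_families(hub48, max_family = 50)
  expect_equal(nrow(out49), nrow(hub48))
})

test_that("family filtering agrees with a label-propagation component oracle", {
  set.seed(99)
  genes <- sprintf("g%03d", 1:200)
  pairs <- data.frame(genome_a = "A", gene_a = sample(genes, 300, TRUE),
                      genome_b = "A", gene_b = sample(genes, 300, TRUE),
                      e_value = 1e-50, bit_score = 200,
                      stringsAsFactors = FALSE)
  pairs <- filter_homolog_pairs(pairs)
  # oracle: iterate label merging until fixed point
  labels <- stats::setNames(seq_along(genes), genes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pairs))) {
      la <- labels[[pairs$gene_a[i]]]; lb <- labels[[pairs$gene_b[i]]]
      if (la != lb) {
        labels[labels == max(la, lb)] <- min(la, lb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(labels[unique(c(pairs$gene_a, pairs$gene_b))])
  for (mf in c(5, 10, 20)) {
    big <- names(labels)[labels %in% names(sizes)[sizes >= mf]]
    keep_oracle <- !(pairs$gene_a %in% big | pairs$gene_b %in% big)
    got <- filter_large_families(pairs, max_family = mf)
    expect_setequal(paste(got$gene_a, got$gene_b),
                    paste(pairs$gene_a, pairs$gene_b)[keep_oracle])
  }
})

test_that("perfect diagonals chain into single blocks; short chains are dropped", {
  a <- toy_annotation("A", 30)
  b <- toy_annotation("B", 30)
  p5 <- toy_pairs(a, b, c(1, 3, 5, 7, 9), c(2, 4, 6, 8, 10))
  bl <- chain_blocks(p5, a, b)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$n_anchors, 5L)
  expect_equal(bl$blocks$orientation, "parallel")
  validate_blocks(bl)

  p3 <- toy_pairs(a, b, c(1, 3, 5), c(2, 4, 6))
  expect_equal(nrow(chain_blocks(p3, a, b)$blocks), 0L)

  # antiparallel diagonal
  pr <- toy_pairs(a, b, 1:6, 12:7)
  blr <- chain_blocks(pr, a, b)
  expect_equal(blr$blocks$orientation, "antiparallel")
  expect_equal(blr$blocks$n_anchors, 6L)
  validate_blocks(blr)

  # a gap of more than 50 intervening genes splits nothing into a block
  a2 <- toy_annotation("A", 200); b2 <- toy_annotation("B", 200)
  pg <- toy_pairs(a2, b2, c(1, 2, 3, 4, 60, 61, 62, 63),
                  c(1, 2, 3, 4, 60, 61, 62, 63))
  blg <- chain_blocks(pg, a2, b2, max_gap = 50)
  expect_equal(sort(blg$blocks$n_anchors), c(4L, 4L))

  expect_equal(nrow(chain_blocks(p5[0, ], a, b)$blocks), 0L)
})

test_that("chaining equals the recursive-DP oracle on random instances", {
  for (seed in 1:12) {
    set.seed(seed)
    n_noise <- sample(10:35, 1)
    diag_len <- sample(10:25, 1)
    na <- 200
    oa <- c(seq_len(diag_len) * 3, sample.int(na, n_noise, replace = FALSE))
    ob <- c(seq_len(diag_len) * 3 + 5, sample.int(na, n_noise))
    keep <- !duplicated(paste(oa, ob))
    oa <- oa[keep]; ob <- ob[keep]
    a <- toy_annotation("A", na + 10)
    b <- toy_annotation("B", na + 10)
    pairs <- toy_pairs(a, b, oa, ob)
    got <- chain_blocks(pairs, a, b, max_gap = 50, min_anchors = 4)
    want <- oracle_extract_blocks(oa - 1L, ob - 1L, max_gap = 50,
                                  min_anchors = 4)
    expect_equal(nrow(got$blocks), length(want))
    got_sets <- lapply(got$blocks$block_id, function(id) {
      an <- got$anchors[got$anchors$block_id == id, ]
      sort(paste(an$order_a, an$order_b))
    })
    want_sets <- lapply(want, function(w)
      sort(paste(oa[w$anchors] - 1L, ob[w$anchors] - 1L)))
    expect_equal(got_sets, want_sets)
    expect_equal(got$blocks$orientation,
                 vapply(want, `[[`, character(1), "orientation"))
    validate_blocks(got)
  }
})

test_that("maximal chain length matches exhaustive enumeration at tiny n", {
  for (seed in 1:4) {
    set.seed(100 + seed)
    n <- 10
    oa <- sample.int(40, n); ob <- sample.int(40, n)
    keep <- !duplicated(paste(oa, ob))
    oa <- oa[keep]; ob <- ob[keep]
    a <- toy_annotation("A", 45); b <- toy_annotation("B", 45)
    got <- chain_blocks(toy_pairs(a, b, oa, ob), a, b,
                        max_gap = 50, min_anchors = 1)
    best_got <- if (nrow(got$blocks) > 0) max(got$blocks$n_anchors) else 0L
    expect_equal(best_got,
                 oracle_exhaustive_max_chain(oa - 1L, ob - 1L, max_gap = 50))
  }
})

test_that("block Ks medians follow the anchor median with NAs ignored", {
  a <- toy_annotation("A", 30); b <- toy_annotation("B", 30)
  bl <- chain_blocks(toy_pairs(a, b, 1:5, 1:5), a, b)
  an <- bl$anchors
  ks3 <- data.frame(gene_a = an$gene_a[1:3], gene_b = an$gene_b[1:3],
                    ks = c(0.5, 0.7, 0.9))
  expect_equal(annotate_block_ks(bl, ks3)$blocks$median_ks, 0.7)
  ks2 <- data.frame(gene_a = an$gene_a[1:2], gene_b = an$gene_b[1:2],
                    ks = c(0.5, 0.7))
  expect_equal(annotate_block_ks(bl, ks2)$blocks$median_ks, 0.6)
  # reversed gene order in the ks table still matches
  ks_rev <- data.frame(gene_a = an$gene_b[1:3], gene_b = an$gene_a[1:3],
                       ks = c(0.5, 0.7, 0.9))
  expect_equal(annotate_block_ks(bl, ks_rev)$blocks$median_ks, 0.7)
  # no Ks at all: flagged, median NA
  none <- annotate_block_ks(bl, ks3[0, ])
  expect_true(is.na(none$blocks$median_ks))
  expect_true(none$blocks$ks_flagged)
})

test_that("blocks are classified to the nearest peak in sigma units", {
  a <- toy_annotation("A", 30); b <- toy_annotation("B", 30)
  bl <- chain_blocks(toy_pairs(a, b, 1:5, 1:5), a, b)
  an <- bl$anchors
  bl <- annotate_block_ks(bl, data.frame(gene_a = an$gene_a,
                                         gene_b = an$gene_b, ks = 1.20))
  peaks <- data.frame(event = c("divergence", "ECH"),
                      mu = c(1.23, 1.50), sigma = c(0.1, 0.1))
  cl <- classify_block_event(bl, peaks)
  expect_equal(cl$blocks$event_label, "divergence")

  # cross-genome block nearest a non-divergence peak is an outparalog
  bl2 <- annotate_block_ks(bl, data.frame(gene_a = an$gene_a,
                                          gene_b = an$gene_b, ks = 1.49))
  expect_equal(classify_block_event(bl2, peaks)$blocks$event_label,
               "outparalog")

  # exact tie in sigma units: smaller mean wins, flagged
  tie_peaks <- data.frame(event = c("divergence", "ECH"),
                          mu = c(1.0, 1.4), sigma = c(0.1, 0.1))
  bl3 <- annotate_block_ks(bl, data.frame(gene_a = an$gene_a,
                                          gene_b = an$gene_b, ks = 1.2))
  cl3 <- classify_block_event(bl3, tie_peaks)
  expect_equal(cl3$blocks$event_label, "divergence")
  expect_true(cl3$blocks$tie_flagged)
})

test_that("event labels recover the generating event at 4-sigma separation", {
  set.seed(21)
  n <- 150
  spacing <- 60  # beyond the gap limit, so segments stay separate blocks
  a <- toy_annotation("A", n * spacing + 10)
  b <- toy_annotation("B", n * spacing + 10)
  truth <- sample(c("divergence", "outparalog"), n, replace = TRUE)
  mu <- c(divergence = 1.0, outparalog = 1.8)  # 4 sigma apart at 0.2
  rows <- lapply(seq_len(n), function(i) {
    o <- (i - 1) * spacing + 1:5
    toy_pairs(a, b, o, o)
  })
  bl <- chain_blocks(do.call(rbind, rows), a, b)
  expect_equal(nrow(bl$blocks), n)
  # locate each block's generating segment by its anchor span
  seg_of <- vapply(bl$blocks$block_id, function(id) {
    an <- bl$anchors[bl$anchors$block_id == id, ]
    as.integer(min(an$order_a) %/% spacing + 1L)
  }, integer(1))
  bl$blocks$median_ks <- stats::rnorm(n, mu[truth[seg_of]], 0.2)
  bl$blocks$ks_flagged <- FALSE
  peaks <- data.frame(event = c("divergence", "outparalog"),
                      mu = unname(mu), sigma = 0.2)
  cl <- classify_block_event(bl, peaks)
  expect_gte(mean(cl$blocks$event_label == truth[seg_of]), 0.95)
})

test_that("orthologous depth ratio recovers 1:3 and errors without blocks", {
  cfg <- sim_config(seed = 8, n_genes = 900, n_chromosomes = 3,
                    retention = c(LF = 1, MF1 = 1, MF2 = 1),
                    n_planted_svs = 0)
  res <- run_pipeline(cfg)
  dr <- res$per_hex$hexA$depth_ratio
  expect_equal(dr$reduced, "1:3")
  expect_equal(dr$depth_a, 1L)
  expect_equal(dr$depth_b, 3L)

  # no orthologous labels -> error
  bl <- res$per_hex$hexA$blocks
  bl$blocks$event_label <- "unassigned"
  expect_error(infer_depth_ratio(bl, res$dataset$ref,
                                 res$dataset$hexaploids$hexA$annotation),
               "no orthologous blocks")
})
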