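test_that("TSV annotations are read with rank order indices", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chromosome\tgene_id\tstart\tend\tstrand",
               "c1\tg1\t100\t200\t+",
               "c1\tg2\t300\t400\t-",
               "c1\tg3\t500\t600\t+"), f)
  ann <- read_gene_annotation(f, "toy")
  expect_s3_class(ann, "genome_annotation")
  expect_equal(ann$genes$order_index, c(0L, 1L, 2L))
  expect_equal(ann$genes$gene_id, c("g1", "g2", "g3"))
})

test_that("GFF3 genes are sorted by start before ranking", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t500\t900\t.\t+\t.\tID=gA",
               "chr1\tsrc\tgene\t100\t300\t.\t-\t.\tID=gB",
               "chr1\tsrc\tmRNA\t100\t300\t.\t-\t.\tID=gB.t1;Parent=gB"), f)
  ann <- read_gene_annotation(f, "toy")
  g <- ann$genes
  expect_equal(g$order_index[g$gene_id == "gA"], 1L)
  expect_equal(g$order_index[g$gene_id == "gB"], 0L)
  expect_equal(g$strand[g$gene_id == "gB"], "-")
})

test_that("annotation invariants are enforced", {
  expect_error(
    genome_annotation(data.frame(chromosome = "c1",
                                 gene_id = c("dup", "dup"),
                                 start = c(1, 100), end = c(50, 150)),
                      "toy"),
    "dup")
  expect_error(
    genome_annotation(data.frame(chromosome = "c1", gene_id = "g",
                                 start = 100, end = 50), "toy"),
    "end < start")
  # tie on start broken lexicographically by gene_id
  ann <- genome_annotation(data.frame(chromosome = "c1",
                                      gene_id = c("b", "a"),
                                      start = c(10, 10), end = c(20, 20)),
                           "toy")
  expect_equal(ann$genes$gene_id, c("a", "b"))
})

test_that("annotations round-trip through write and read", {
  ds <- simulate_hexaploid_dataset(sim_config(seed = 11, n_genes = 120,
                                              n_chromosomes = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_annotation(ds$ref, f)
  back <- read_gene_annotation(f, ds$ref$genome_id)
  expect_identical(back$genes, ds$ref$genes)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_annotation(ds$hexaploids$hexA$annotation, f2)
  back2 <- read_gene_annotation(f2, "HexA")
  expect_identical(back2$genes, ds$hexaploids$hexA$annotation$genes)
})

test_that("homolog tables are threshold-filtered and canonicalized", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(42)
  n <- 100
  scores <- c(rep(50, 37), rep(150, 63))[sample.int(n)]
  rows <- sprintf("q%03d\ts%03d\t90\t100\t5\t1\t1\t100\t1\t100\t1e-20\t%g",
                  seq_len(n), seq_len(n), scores)
  writeLines(rows, f)
  pairs <- read_homolog_table(f, "A", "B")
  # independent recount of the surviving rows
  raw <- utils::read.table(f, sep = "\t")
  expect_equal(nrow(pairs), sum(raw$V12 > 100 & raw$V11 < 1e-5))
  expect_equal(nrow(pairs), 63)

  # an E-value at 1e-3 fails the threshold
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t90\t100\t5\t1\t1\t100\t1\t100\t1e-3\t500",
               "q2\ts2\t90\t100\t5\t1\t1\t100\t1\t100\t1e-20\t500"), f2)
  expect_equal(read_homolog_table(f2, "A", "B")$gene_a, "q2")

  # empty file, malformed rows
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f3)
  expect_equal(nrow(read_homolog_table(f3, "A", "B")), 0L)
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("broken line",
               "q1\ts1\t90\t100\t5\t1\t1\t100\t1\t100\t1e-20\t500"), f4)
  expect_warning(p4 <- read_homolog_table(f4, "A", "B"), "1 malformed")
  expect_equal(nrow(p4), 1L)
})

test_that("pair filtering is idempotent and collapses reciprocals", {
  pairs <- data.frame(
    genome_a = "A", gene_a = c("g2", "g1", "g3", "g3"),
    genome_b = "A", gene_b = c("g1", "g2", "g3", "g4"),
    e_value = 1e-20, bit_score = c(150, 200, 300, 120),
    stringsAsFactors = FALSE)
  once <- filter_homolog_pairs(pairs)
  expect_equal(nrow(once), 2L)  # reciprocal collapsed, self-hit dropped
  expect_equal(once$bit_score[once$gene_a == "g1"], 200)  # best kept
  expect_true(all(once$gene_a < once$gene_b))
  expect_identical(filter_homolog_pairs(once), once)
})

test_that("homolog tables round-trip through the writer", {
  ds <- simulate_hexaploid_dataset(sim_config(seed = 5, n_genes = 100,
                                              n_chromosomes = 2))
  p <- ds$pairs[ds$pairs$genome_a == "Ref" & ds$pairs$genome_b == "HexA",
                c("genome_a", "gene_a", "genome_b", "gene_b",
                  "e_value", "bit_score")]
  p <- filter_homolog_pairs(p)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_homolog_table(p, f)
  back <- read_homolog_table(f, "Ref", "HexA")
  expect_identical(back[order(back$gene_a, back$gene_b), ],
                   p[order(p$gene_a, p$gene_b), ])
})

test_that("codon alignments pair consecutive FASTA records and validate", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ATGGATGAT", ">b", "ATGGATGAC"), f)
  alns <- read_codon_alignments(f)
  expect_length(alns, 1L)
  expect_equal(nchar(alns[[1]]$seq_a) / 3, 3)

  writeLines(c(">a", "ATGGATGAT", ">b", "ATGGATGAC", ">c", "ATG"), f)
  expect_error(read_codon_alignments(f), "odd number")

  writeLines(c(">a", "ATGGATGAT", ">b", "ATGGAT"), f)
  expect_error(read_codon_alignments(f), "lengths differ")

  writeLines(c(">a", "ATGG", ">b", "ATGC"), f)
  expect_error(read_codon_alignments(f), "multiple of 3")
})

test_that("simulated codon alignments round-trip through FASTA", {
  cfg <- sim_config(seed = 7, n_genes = 30, n_chromosomes = 1,
                    ks_mode = "codon_evolution", n_ech_pairs = 5)
  ds <- simulate_hexaploid_dataset(cfg)
  alns <- ds$alignments[1:50]
  f <- withr::local_tempfile(fileext = ".fa")
  write_codon_alignments(alns, f)
  back <- read_codon_alignments(f)
  expect_length(back, 50L)
  for (i in c(1, 25, 50)) {
    expect_equal(back[[i]]$seq_a, alns[[i]]$seq_a)
    expect_equal(back[[i]]$seq_b, alns[[i]]$seq_b)
  }
})
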