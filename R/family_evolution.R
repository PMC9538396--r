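#' @title Gene-family expansion and subgenome placement
#' @description Classifies family members by duplication origin (polyploidy
#'   versus tandem duplication versus retained ancestral copies), computes
#'   whole-genome-duplication and tandem-duplication expansion rates and the
#'   gene-loss contraction rate relative to the outgroup family size, and
#'   places members into subgenomes.
#' @name family_evolution
NULL

#' Label family members by duplication origin
#'
#' A member anchored in a polyploidy-labelled block whose partner is also a
#' family member is `wgd_gained`; a member within `tandem_max_gap`
#' intervening genes of another member on the same chromosome is
#' `tandem_gained` (the downstream copy of each tandem cluster is the gained
#' one; the first member of the cluster keeps its other label); a member
#' syntenic (in any block) to a reference-genome family member is
#' `retained_ancestral`; anything else is `unknown`. Precedence:
#' tandem > wgd > retained.
#'
#' @param family data.frame with columns `gene_id`, `genome`.
#' @param blocks a classified `synteny_blocks` object (may pool several
#'   genome pairs via `rbind` of anchors/blocks).
#' @param annotations named list of [genome_annotation()] objects.
#' @param ref_genome outgroup genome id.
#' @param wgd_events block labels counted as polyploidy events.
#' @param tandem_max_gap maximum intervening genes for a tandem pair.
#' @return data.frame: gene_id, genome, origin.
#' @export
label_origins <- function(family, blocks, annotations, ref_genome,
                          wgd_events = c("SCH", "CCH", "ECH"),
                          tandem_max_gap = 5) {
  stopifnot(all(c("gene_id", "genome") %in% names(family)))
  fam_key <- paste(family$genome, family$gene_id, sep = "\r")
  origin <- rep("unknown", nrow(family))
  # annotation lookup
  for (i in seq_len(nrow(family))) {
    ann <- annotations[[family$genome[i]]]
    if (is.null(ann) || !family$gene_id[i] %in% ann$genes$gene_id) {
      stop("family member absent from annotation: ", family$gene_id[i])
    }
  }
  b <- blocks$blocks
  an <- merge(blocks$anchors, b[, c("block_id", "genome_a", "genome_b",
                                    "event_label")], by = "block_id")
  ka <- paste(an$genome_a, an$gene_a, sep = "\r")
  kb <- paste(an$genome_b, an$gene_b, sep = "\r")
  # retained ancestral: syntenic to a reference family member
  ref_members <- fam_key[family$genome == ref_genome]
  retained <- (ka %in% ref_members & kb %in% fam_key) |
    (kb %in% ref_members & ka %in% fam_key)
  retained_genes <- unique(c(ka[retained], kb[retained]))
  origin[fam_key %in% setdiff(retained_genes, ref_members)] <-
    "retained_ancestral"
  origin[family$genome == ref_genome] <- "retained_ancestral"
  # wgd gained: anchored in a polyploidy block paralogous to another member
  wgd <- an$event_label %in% wgd_events & ka %in% fam_key & kb %in% fam_key &
    an$genome_a == an$genome_b
  wgd_genes <- unique(c(ka[wgd], kb[wgd]))
  origin[fam_key %in% wgd_genes] <- "wgd_gained"
  # tandem gained: near another member on the same chromosome; the
  # downstream copy of each adjacent pair is the gained one
  for (g in unique(family$genome)) {
    ann <- annotations[[g]]
    members <- family$gene_id[family$genome == g]
    gi <- ann$genes[ann$genes$gene_id %in% members, ]
    gi <- gi[order(gi$chromosome, gi$order_index), ]
    if (nrow(gi) < 2) next
    for (i in 2:nrow(gi)) {
      same <- gi$chromosome[i] == gi$chromosome[i - 1]
      gap <- gi$order_index[i] - gi$order_index[i - 1] - 1L
      if (same && gap <= tandem_max_gap) {
        origin[fam_key == paste(g, gi$gene_id[i], sep = "\r")] <-
          "tandem_gained"
      }
    }
  }
  data.frame(gene_id = family$gene_id, genome = family$genome,
             origin = origin, stringsAsFactors = FALSE)
}

#' Family expansion and contraction rates
#'
#' With `N = (reference family size) - (reference tandem-gained members)` as
#' the ancestral baseline:
#' `WGD-ER = 100 * (target wgd_gained) / N`,
#' `TD-ER = 100 * (reference tandem_gained) / N`,
#' `CR = 100 * (reference genes lost in the target lineage) / N`.
#' The loss count is taken from `lost_in_target` when supplied, otherwise
#' inferred from `blocks` as reference family members with no syntenic
#' family partner in the target genome.
#'
#' @param labels a [label_origins()] result.
#' @param ref_genome,target_genome genome ids.
#' @param blocks optional classified `synteny_blocks` for loss inference.
#' @param lost_in_target optional explicit loss count.
#' @return list of class `expansion_rates`: `n_baseline`, `wgd_er`, `td_er`,
#'   `cr` (percent).
#' @export
expansion_rates <- function(labels, ref_genome, target_genome,
                            blocks = NULL, lost_in_target = NULL) {
  ref <- labels[labels$genome == ref_genome, , drop = FALSE]
  tgt <- labels[labels$genome == target_genome, , drop = FALSE]
  td_ref <- sum(ref$origin == "tandem_gained")
  n <- nrow(ref) - td_ref
  if (n == 0) stop("baseline N = 0")
  if (is.null(lost_in_target)) {
    if (is.null(blocks)) {
      lost_in_target <- 0L
    } else {
      an <- merge(blocks$anchors,
                  blocks$blocks[, c("block_id", "genome_a", "genome_b")],
                  by = "block_id")
      cross <- an[(an$genome_a == ref_genome & an$genome_b == target_genome) |
                    (an$genome_b == ref_genome & an$genome_a == target_genome),
                  , drop = FALSE]
      has_partner <- vapply(ref$gene_id, function(gid) {
        hit <- (cross$genome_a == ref_genome & cross$gene_a == gid &
                  cross$gene_b %in% tgt$gene_id) |
          (cross$genome_b == ref_genome & cross$gene_b == gid &
             cross$gene_a %in% tgt$gene_id)
        any(hit)
      }, logical(1))
      lost_in_target <- sum(!has_partner)
    }
  }
  structure(list(
    n_baseline = n,
    wgd_er = 100 * sum(tgt$origin == "wgd_gained") / n,
    td_er = 100 * td_ref / n,
    cr = 100 * lost_in_target / n
  ), class = "expansion_rates")
}

#' Place family members into subgenomes
#'
#' A member's subgenome is the LF/MF1/MF2 label of the slot whose block
#' contains it (via the slot map); members outside any assigned region are
#' `none`. Percentages are reported to one decimal.
#'
#' @param family data.frame with columns `gene_id`, `genome`.
#' @param slot_map an [assign_slots()] result.
#' @param assignment an [assign_subgenomes()] result.
#' @param genome target genome id.
#' @param ref_ann reference [genome_annotation()] (locates each anchor's
#'   reference chromosome, whose slot ranking names the subgenome).
#' @return data.frame: subgenome, count, percent (rows LF, MF1, MF2, none).
#' @export
subgenome_placement <- function(family, slot_map, assignment, genome,
                                ref_ann) {
  members <- family$gene_id[family$genome == genome]
  if (length(members) == 0) {
    return(data.frame(subgenome = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  m <- slot_map$map[slot_map$map$genome == genome, , drop = FALSE]
  chrom_of <- stats::setNames(ref_ann$genes$chromosome,
                              ref_ann$genes$gene_id)
  labs <- vapply(members, function(gid) {
    hit <- m[m$target_gene == gid, , drop = FALSE]
    if (nrow(hit) == 0) return("none")
    chr <- chrom_of[[hit$ref_gene[1]]]
    lab <- assignment$label[assignment$chromosome == chr &
                              assignment$slot == hit$slot[1]]
    if (length(lab) == 0) "none" else lab[1]
  }, character(1))
  counts <- table(factor(labs, levels = c("LF", "MF1", "MF2", "none")))
  data.frame(subgenome = names(counts),
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / length(members), 1),
             stringsAsFactors = FALSE)
}
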