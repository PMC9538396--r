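#' Run the full analysis on a simulated dataset
#'
#' End-to-end driver mirroring the analysis workflow: homolog filtering,
#' synteny chaining per genome pair, per-sample Ks peak fitting, event
#' classification of blocks, depth ratios, evolutionary-rate correction and
#' event dating, alignment-table construction, subgenome assignment,
#' retention and P-index statistics, geometric loss-run fitting, breakpoint
#' detection and the two-step verdict.
#'
#' @param config a [sim_config()]; the dataset is generated under its seed.
#' @param dataset optionally, an existing [simulate_hexaploid_dataset()]
#'   result (config is then ignored).
#' @param max_gap,min_anchors synteny chaining parameters.
#' @return list with the intermediate and final results of every stage.
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         max_gap = 50, min_anchors = 4) {
  if (is.null(dataset)) dataset <- simulate_hexaploid_dataset(config)
  cfg <- dataset$config
  ref <- dataset$ref
  anns <- c(stats::setNames(list(ref), ref$genome_id),
            stats::setNames(lapply(dataset$hexaploids,
                                   function(h) h$annotation),
                            vapply(dataset$hexaploids,
                                   function(h) h$annotation$genome_id,
                                   character(1))))
  pairs <- filter_homolog_pairs(dataset$pairs)
  ks_tab <- dataset$pairs[, c("gene_a", "gene_b", "ks")]

  pair_key <- paste(pairs$genome_a, pairs$genome_b, sep = "\r")
  comparisons <- unique(pair_key)
  blocks <- list(); peaks <- list()
  for (cmp in comparisons) {
    gs <- strsplit(cmp, "\r", fixed = TRUE)[[1]]
    # family filtering is per comparison, as each genome pair is an
    # independent homology search
    sel <- filter_large_families(pairs[pair_key == cmp, , drop = FALSE])
    bl <- chain_blocks(sel, anns[[gs[1]]], anns[[gs[2]]],
                       max_gap = max_gap, min_anchors = min_anchors)
    bl <- annotate_block_ks(bl, ks_tab)
    nm <- paste(gs, collapse = "__")
    blocks[[nm]] <- bl
    ks_sample <- stats::setNames(
      dataset$pairs$ks[dataset$pairs$genome_a == gs[1] &
                         dataset$pairs$genome_b == gs[2]], NULL)
    peaks[[nm]] <- tryCatch(ks_peaks(ks_sample, seed = cfg$seed),
                            error = function(e) NULL)
  }

  # event peak tables and block classification
  hex_ids <- vapply(dataset$hexaploids, function(h) h$annotation$genome_id,
                    character(1))
  ech_peaks <- c()
  classified <- list()
  for (nm in names(blocks)) {
    gs <- strsplit(nm, "__", fixed = TRUE)[[1]]
    pk <- peaks[[nm]]
    if (is.null(pk)) { classified[[nm]] <- blocks[[nm]]; next }
    comp <- pk$components
    if (gs[1] == gs[2]) {
      # within-genome: largest-mean component is the shared ancient event,
      # a smaller one (if present) the internal WGD
      comp <- comp[order(comp$mu), ]
      ech_peaks[gs[1]] <- comp$mu[nrow(comp)]
      ev <- data.frame(event = c(if (nrow(comp) > 1) "wgd", "ECH"),
                       mu = comp$mu[c(if (nrow(comp) > 1) 1, nrow(comp))],
                       sigma = comp$sigma[c(if (nrow(comp) > 1) 1,
                                            nrow(comp))])
    } else {
      # cross-genome: dominant component is the divergence peak
      main <- which.max(comp$weight)
      ev <- data.frame(event = "divergence", mu = comp$mu[main],
                       sigma = comp$sigma[main])
    }
    classified[[nm]] <- classify_block_event(blocks[[nm]], ev)
  }

  rates <- if (length(ech_peaks) >= 2) rate_correction_table(ech_peaks) else
    NULL
  dates <- NULL
  if (!is.null(rates)) {
    mu_g <- rates$mu_g[1]
    lam <- stats::setNames(rates$lambda, rates$genome_id)
    rows <- list()
    for (g in names(ech_peaks)) {
      nm <- paste(g, g, sep = "__")
      pk <- peaks[[nm]]
      if (is.null(pk) || nrow(pk$components) < 2) next
      mu_wgd <- pk$components$mu[1]
      mu_c <- correct_inner_wgd_peak(mu_wgd, ech_peaks[[g]], mu_g)
      dt <- date_event(mu_c, mu_g)
      rows[[length(rows) + 1L]] <- data.frame(
        event = paste0(g, "_wgd"), mu_raw = mu_wgd, mu_corrected = mu_c,
        age_lo = dt$age_lo, age_hi = dt$age_hi, stringsAsFactors = FALSE)
    }
    for (nm in names(peaks)) {
      gs <- strsplit(nm, "__", fixed = TRUE)[[1]]
      if (gs[1] == gs[2]) next
      pk <- peaks[[nm]]
      if (is.null(pk)) next
      if (!all(gs %in% names(lam))) next
      main <- which.max(pk$components$weight)
      mu_raw <- pk$components$mu[main]
      mu_c <- correct_between_peak(mu_raw, lam[[gs[1]]], lam[[gs[2]]])
      dt <- date_event(mu_c, mu_g)
      rows[[length(rows) + 1L]] <- data.frame(
        event = paste0(nm, "_divergence"), mu_raw = mu_raw,
        mu_corrected = mu_c, age_lo = dt$age_lo, age_hi = dt$age_hi,
        stringsAsFactors = FALSE)
    }
    dates <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  }

  # per-hexaploid downstream analyses against the reference
  per_hex <- list()
  for (hk in names(dataset$hexaploids)) {
    gid <- dataset$hexaploids[[hk]]$annotation$genome_id
    nm <- paste(ref$genome_id, gid, sep = "__")
    bl <- classified[[nm]]
    if (is.null(bl) || nrow(bl$blocks) == 0) next
    sm <- assign_slots(bl, ref)
    tab <- build_table(sm, ref, gid)
    asg <- assign_subgenomes(tab, gid)
    prof <- retention_profile(tab, asg, gid)
    hist_all <- loss_run_histogram(tab, asg, gid)
    geo <- tryCatch(fit_geometric(hist_all), error = function(e) NULL)
    pind <- tryCatch(pindex_from_table(tab, asg, gid),
                     error = function(e) NULL)
    bp <- detect_breakpoints(bl, sm, asg, ref)
    verdict <- shared_breakpoints(bp)
    depth <- tryCatch(
      infer_depth_ratio(bl, ref, dataset$hexaploids[[hk]]$annotation),
      error = function(e) NULL)
    per_hex[[hk]] <- list(blocks = bl, slot_map = sm, table = tab,
                          assignment = asg, profile = prof,
                          loss_runs = hist_all, geometric = geo,
                          pindex = pind, breakpoints = bp,
                          verdict = verdict, depth_ratio = depth)
  }

  list(dataset = dataset, pairs = pairs, blocks = classified,
       peaks = peaks, ech_peaks = ech_peaks, rates = rates, dates = dates,
       per_hex = per_hex)
}
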