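#' @title Synonymous-substitution (Ks) estimation and peak localisation
#' @description Per-pair Ks/Ka by Nei-Gojobori (NG86) counting with
#'   Jukes-Cantor correction, Gaussian kernel-density estimation of Ks
#'   samples, and mixture-of-Gaussians curve fitting to locate event peaks.
#' @name ks_engine
NULL

# Shared genetic-code table (standard code); "*" marks stops.
.GC <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
})

.codon_cache <- new.env(parent = emptyenv())

# Fraction of synonymous sites of one codon: at each of the 3 positions, the
# fraction of the 3 possible single-nucleotide changes that preserve the
# amino acid. Changes creating a stop codon count as nonsynonymous.
.syn_fraction <- function(codon) {
  key <- paste0("s:", codon)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- .GC[[codon]]
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == chars[pos]) next
      alt <- chars; alt[pos] <- b
      alt_aa <- .GC[[paste(alt, collapse = "")]]
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  assign(key, s, envir = .codon_cache)
  s
}

# All permutations of 1..k (k <= 3) in lexicographic order.
.perms <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all equally-weighted single-substitution pathways. Pathways passing through
# a stop codon are excluded; if every pathway is blocked, all pathways are
# used with steps into/out of stops counted as nonsynonymous.
.pathway_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("p:", c1, c2)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  x1 <- strsplit(c1, "")[[1]]; x2 <- strsplit(c2, "")[[1]]
  pos <- which(x1 != x2)
  k <- length(pos)
  walk <- function(order_pos) {
    cur <- x1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order_pos) {
      nxt <- cur; nxt[p] <- x2[p]
      aa_cur <- .GC[[paste(cur, collapse = "")]]
      aa_nxt <- .GC[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") blocked <- TRUE
      if (aa_cur != "*" && aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  paths <- lapply(.perms(k), function(pm) walk(pos[pm]))
  open <- Filter(function(p) !p$blocked, paths)
  use <- if (length(open) > 0) open else paths
  res <- c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
           nd = mean(vapply(use, `[[`, numeric(1), "nd")))
  assign(key, res, envir = .codon_cache)
  res
}

#' Ks and Ka for one codon alignment by Nei-Gojobori counting
#'
#' Synonymous site fractions are computed per codon (changes to stop codons
#' count as nonsynonymous) and averaged over the two sequences. Differences
#' between codons are averaged over all equally-weighted substitution
#' pathways, excluding pathways through stop codons. Codons containing gaps,
#' ambiguity characters, or a stop in either sequence are excluded from
#' counting. Proportions are corrected by Jukes-Cantor,
#' `d = -(3/4) * log(1 - (4/3) * p)`; a proportion with `(4/3) p >= 1` sets
#' the corresponding `saturated` flag and leaves the estimate `NA`.
#'
#' @param alignment a [codon_alignment()].
#' @return list of class `ks_value`: `pair_id`, `ks`, `ka`, `syn_sites` (S),
#'   `nonsyn_sites` (N), `syn_diffs` (Sd), `nonsyn_diffs` (Nd), `codons`
#'   (comparable codon count), `saturated_ks`, `saturated_ka`.
#' @export
ng86_ks <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  a <- alignment$seq_a; b <- alignment$seq_b
  n_cod <- nchar(a) %/% 3
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0; used <- 0L
  ok_base <- c("A", "C", "G", "T")
  for (i in seq_len(n_cod)) {
    c1 <- substr(a, 3 * i - 2, 3 * i)
    c2 <- substr(b, 3 * i - 2, 3 * i)
    ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
    if (!all(ch1 %in% ok_base) || !all(ch2 %in% ok_base)) next
    if (.GC[[c1]] == "*" || .GC[[c2]] == "*") next
    used <- used + 1L
    S1 <- S1 + .syn_fraction(c1)
    S2 <- S2 + .syn_fraction(c2)
    d <- .pathway_diffs(c1, c2)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  if (used == 0L) stop("alignment '", alignment$pair_id,
                       "': no comparable codons")
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  jc <- function(p) {
    if (4 / 3 * p >= 1) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc(ps); ka <- jc(pn)
  structure(list(
    pair_id = alignment$pair_id, ks = ks, ka = ka,
    syn_sites = S, nonsyn_sites = N, syn_diffs = Sd, nonsyn_diffs = Nd,
    codons = used, saturated_ks = is.na(ks), saturated_ka = is.na(ka)
  ), class = "ks_value")
}

#' NG86 Ks for a list of codon alignments
#'
#' @param alignments list of [codon_alignment()] objects.
#' @return data.frame with one row per alignment (pair_id, ks, ka, S, N, Sd,
#'   Nd, saturated flags).
#' @export
ng86_ks_table <- function(alignments) {
  rows <- lapply(alignments, function(al) {
    v <- ng86_ks(al)
    data.frame(pair_id = v$pair_id, ks = v$ks, ka = v$ka,
               syn_sites = v$syn_sites, nonsyn_sites = v$nonsyn_sites,
               syn_diffs = v$syn_diffs, nonsyn_diffs = v$nonsyn_diffs,
               saturated_ks = v$saturated_ks, saturated_ka = v$saturated_ka,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian kernel-density curve of a Ks sample
#'
#' Values outside `fit_range` (by default excluding near-zero identical-pair
#' inflation and the saturated tail beyond 3) are dropped before smoothing.
#' The kernel width follows the standard deviation convention of
#' [stats::density()].
#'
#' @param ks numeric vector of Ks values (NA allowed; dropped).
#' @param bandwidth kernel smoothing width (standard deviation of the
#'   Gaussian kernel), in Ks units.
#' @param fit_range numeric length-2, values retained are in
#'   `(fit_range[1], fit_range[2]]`.
#' @param n_grid evaluation grid size.
#' @param min_n minimum number of usable values.
#' @return list of class `ks_density`: `x`, `y`, `n`, `bandwidth`,
#'   `fit_range`.
#' @export
kde_curve <- function(ks, bandwidth = 0.05, fit_range = c(0.005, 3),
                      n_grid = 512, min_n = 30) {
  ks <- ks[is.finite(ks)]
  ks <- ks[ks > fit_range[1] & ks <= fit_range[2]]
  if (length(ks) < min_n) {
    stop("too few Ks values in fit range: ", length(ks), " < ", min_n)
  }
  d <- stats::density(ks, bw = bandwidth, kernel = "gaussian",
                      from = fit_range[1], to = fit_range[2], n = n_grid)
  structure(list(x = d$x, y = d$y, n = length(ks), bandwidth = bandwidth,
                 fit_range = fit_range), class = "ks_density")
}

.mixture_predict <- function(x, mu, sigma, w) {
  y <- numeric(length(x))
  for (j in seq_along(mu)) y <- y + w[j] * stats::dnorm(x, mu[j], sigma[j])
  y
}

.mixture_sse <- function(par, x, y, k) {
  mu <- par[seq_len(k)]
  sigma <- exp(par[k + seq_len(k)])
  w <- exp(par[2 * k + seq_len(k)])
  sum((y - .mixture_predict(x, mu, sigma, w))^2)
}

#' Fit a Gaussian mixture curve to a Ks density
#'
#' Least-squares fit of a sum of Gaussians to the kernel-density curve (the
#' statistic of interest is the curve shape, so the fit minimises squared
#' error on the density grid rather than a sample likelihood). Components are
#' added one at a time until the coefficient of determination
#' `R^2 = 1 - SSE/SST` reaches `r2_min`; the smallest sufficient component
#' count is returned. Each component count is fitted from `n_starts`
#' deterministic multi-starts (quantile-spread means with seeded jitter) and
#' the best SSE kept. If `r2_min` is unreachable at `max_components` the best
#' fit is returned flagged `accepted = FALSE`.
#'
#' @param curve a [kde_curve()] result.
#' @param max_components largest mixture size tried.
#' @param r2_min acceptance threshold on R-squared.
#' @param n_starts deterministic multi-start count per component number.
#' @param seed base seed for start jitter.
#' @return list of class `ks_mixture`: `components` (data.frame mu, sigma,
#'   weight, sorted by mu), `n_components`, `r_squared`, `accepted`,
#'   `bandwidth`, `fit_range`.
#' @export
fit_mixture <- function(curve, max_components = 4, r2_min = 0.95,
                        n_starts = 10, seed = 1) {
  stopifnot(inherits(curve, "ks_density"))
  x <- curve$x; y <- curve$y
  dx <- mean(diff(x))
  total_mass <- sum(y) * dx
  sst <- sum((y - mean(y))^2)
  cum <- cumsum(y) / sum(y)
  best_overall <- NULL
  for (k in seq_len(max_components)) {
    # base start: means at evenly spaced mass quantiles
    qs <- (2 * seq_len(k) - 1) / (2 * k)
    mu0 <- vapply(qs, function(q) x[which.min(abs(cum - q))], numeric(1))
    sigma0 <- rep(max(diff(range(x)) / (4 * k), 2 * dx), k)
    w0 <- rep(total_mass / k, k)
    best_k <- NULL
    for (s in seq_len(n_starts)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed * 1000L + s)
      jitter_mu <- if (s == 1) rep(0, k) else
        stats::rnorm(k, 0, diff(range(x)) / (6 * k))
      jitter_s <- if (s == 1) rep(1, k) else exp(stats::rnorm(k, 0, 0.3))
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
      par0 <- c(pmin(pmax(mu0 + jitter_mu, min(x)), max(x)),
                log(sigma0 * jitter_s), log(w0))
      fit <- tryCatch(
        stats::optim(par0, .mixture_sse, x = x, y = y, k = k,
                     method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best_k) || fit$value < best_k$value) best_k <- fit
    }
    if (is.null(best_k)) next
    r2 <- 1 - best_k$value / sst
    model <- list(par = best_k$par, k = k, sse = best_k$value, r2 = r2)
    if (is.null(best_overall) || r2 > best_overall$r2) best_overall <- model
    if (r2 >= r2_min) { best_overall <- model; break }
  }
  if (is.null(best_overall)) stop("mixture fitting failed")
  k <- best_overall$k
  mu <- best_overall$par[seq_len(k)]
  sigma <- exp(best_overall$par[k + seq_len(k)])
  w <- exp(best_overall$par[2 * k + seq_len(k)])
  ord <- order(mu)
  structure(list(
    components = data.frame(mu = mu[ord], sigma = sigma[ord],
                            weight = w[ord]),
    n_components = k,
    r_squared = best_overall$r2,
    accepted = best_overall$r2 >= r2_min,
    bandwidth = curve$bandwidth,
    fit_range = curve$fit_range
  ), class = "ks_mixture")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("<ks_mixture> %d component(s), R^2 = %.4f%s\n",
              x$n_components, x$r_squared,
              if (x$accepted) "" else " (not accepted)"))
  print(x$components)
  invisible(x)
}

#' Locate event Ks peaks in a sample
#'
#' Convenience wrapper: kernel density then mixture fit; returns the fitted
#' component means (event peak estimates) sorted increasing.
#'
#' @inheritParams kde_curve
#' @inheritParams fit_mixture
#' @return a `ks_mixture` object.
#' @export
ks_peaks <- function(ks, bandwidth = 0.05, fit_range = c(0.005, 3),
                     max_components = 4, r2_min = 0.95, seed = 1) {
  fit_mixture(kde_curve(ks, bandwidth = bandwidth, fit_range = fit_range),
              max_components = max_components, r2_min = r2_min, seed = seed)
}
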