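#' Contrast definitions for the genome scan
#'
#' Two scans are run per line: the F0 contrast compares the unexposed
#' founder composite with its LD80 survivors; the F2 contrast compares
#' unexposed F2 with the LD25 and LD75 survivor pools.
#'
#' @param line `"Delt"`, `"Bend"` or `"Feni"`.
#' @param which `"F0"` or `"F2"`.
#' @return List with `label`, `line` and the member `conditions`.
#' @export
fst_contrast <- function(line, which = c("F0", "F2")) {
  line <- match.arg(line, line_levels())
  which <- match.arg(which)
  conditions <- if (which == "F0") {
    c("F0", condition_label(line, "F0_LD80"))
  } else {
    condition_label(line, c("F2", "F2_LD25", "F2_LD75"))
  }
  list(label = paste0(which, "_contrast"), line = line,
       conditions = conditions)
}

#' MCMC schedule for the Bayesian scan
#'
#' The published schedule is 20 pilot runs of 2,000 iterations, a burn-in of
#' 100,000 and 500,000 post-burn-in iterations thinned every 50, with prior
#' odds of 10 for the neutral model. The `"desk"` preset divides all chain
#' lengths by `desk_factor` (default 10) for interactive and test use.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param prior_odds Prior odds of the neutral model.
#' @param pool_size Individuals per pool; read counts are collapsed to an
#'   effective haploid sample of `min(2 * pool_size, depth)` alleles.
#' @param desk_factor Chain-length divisor of the desk preset.
#' @param q_threshold Significance threshold on q-values.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(preset = c("desk", "paper"), prior_odds = 10,
                        pool_size = 100, desk_factor = 10,
                        q_threshold = 0.05) {
  preset <- match.arg(preset)
  div <- if (preset == "desk") desk_factor else 1
  cfg <- list(
    preset = preset, prior_odds = prior_odds, pool_size = pool_size,
    pilot_runs = 20, pilot_length = max(50, round(2000 / div)),
    burn_in = round(1e5 / div), iterations = round(5e5 / div), thin = 50,
    q_threshold = q_threshold
  )
  if (cfg$iterations %% cfg$thin != 0) {
    abort("thinning interval must divide the iteration count")
  }
  structure(cfg, class = c("scan_config", "list"))
}

# collapse read counts of the contrast members into effective haploid allele
# counts; loci with a zero-depth member are dropped with a flag
contrast_matrices <- function(counts, contrast, pool_size,
                              substitutions_only = TRUE) {
  sub <- counts %>%
    dplyr::filter(.data$condition %in% contrast$conditions)
  if (substitutions_only) {
    sub <- sub %>%
      dplyr::filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1,
                    .data$ref != "-", .data$alt != "-")
  }
  wide <- sub %>%
    dplyr::mutate(depth = .data$ref_reads + .data$alt_reads) %>%
    dplyr::select("chrom", "pos", "condition", "depth", "alt_reads") %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("depth", "alt_reads"))
  depth <- as.matrix(wide[, paste0("depth_", contrast$conditions)])
  altr <- as.matrix(wide[, paste0("alt_reads_", contrast$conditions)])
  usable <- rowSums(depth == 0 | is.na(depth)) == 0
  n <- pmin(depth, 2 * pool_size)
  a <- round(altr / depth * n)
  list(
    loci = wide %>% dplyr::select("chrom", "pos") %>%
      dplyr::mutate(skipped = !usable),
    a = matrix(as.integer(a[usable, , drop = FALSE]), ncol = ncol(a)),
    n = matrix(as.integer(n[usable, , drop = FALSE]), ncol = ncol(n))
  )
}

#' Moment-based multi-population F_ST for pooled counts
#'
#' A pool-aware analysis-of-variance estimator on read counts, with the
#' per-pool sample size taken as the effective haploid size
#' `min(2 * pool_size, depth)`. Estimates are clipped to `[0, 1]`; loci with
#' a zero-depth member are returned as `NA` with `skipped = TRUE`.
#'
#' @param counts Long count tibble.
#' @param contrast A [fst_contrast()].
#' @param pool_size Pool size (default 100).
#' @return Tibble (`chrom`, `pos`, `fst`, `skipped`).
#' @export
pooled_fst <- function(counts, contrast, pool_size = 100) {
  m <- contrast_matrices(counts, contrast, pool_size,
                         substitutions_only = FALSE)
  fst <- rep(NA_real_, nrow(m$loci))
  if (nrow(m$a) > 0) {
    n <- m$n
    p <- m$a / n
    J <- ncol(n)
    N <- rowSums(n)
    pbar <- rowSums(n * p) / N
    msp <- rowSums(n * (p - pbar)^2) / (J - 1)
    msg <- rowSums(n * p * (1 - p)) / rowSums(n - 1)
    nc <- (N - rowSums(n^2) / N) / (J - 1)
    est <- (msp - msg) / (msp + (nc - 1) * msg)
    est[!is.finite(est)] <- 0
    fst[!m$loci$skipped] <- pmin(1, pmax(0, est))
  }
  m$loci %>% dplyr::mutate(fst = fst) %>%
    dplyr::select("chrom", "pos", "fst", "skipped")
}

#' q-values from posterior selection probabilities
#'
#' Loci are ranked by decreasing posterior probability; the q-value at rank r
#' is the mean posterior error probability `1 - prob` over ranks 1..r,
#' enforced non-decreasing along the ranking.
#'
#' @param prob Posterior probabilities in `[0, 1]`.
#' @return q-values in the input order.
#' @export
q_values <- function(prob) {
  if (length(prob) == 0) return(numeric(0))
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    abort("posterior probabilities must lie in [0, 1]")
  }
  ord <- order(prob, decreasing = TRUE)
  q_sorted <- cummax(cumsum(1 - prob[ord]) / seq_along(ord))
  q <- numeric(length(prob))
  q[ord] <- q_sorted
  q
}

#' Bayesian F_ST outlier scan
#'
#' Re-implementation of the reversible-jump MCMC genome scan that decomposes
#' locus-by-population differentiation as `logit(F_ij) = alpha_i + beta_j`,
#' with a spike-and-slab prior on the locus effects `alpha_i` (prior odds for
#' the neutral model) and a Dirichlet-multinomial likelihood for the allele
#' counts. Pooled read counts are collapsed to effective haploid samples of
#' `min(2 * pool_size, depth)` alleles. The per-locus posterior probability
#' of selection is the inclusion frequency of `alpha_i` across retained
#' samples; q-values follow [q_values()]. Only substitutions enter the scan.
#'
#' @param counts Long count tibble.
#' @param contrast A [fst_contrast()].
#' @param config A [scan_config()].
#' @return Object of class `fst_scan`: list with `result` (tibble `chrom`,
#'   `pos`, `contrast`, `line`, `fst`, `post_prob`, `alpha`, `q`,
#'   `skipped`), `beta`, `split_disagreement`, `converged` and `config`.
#' @export
bayes_scan <- function(counts, contrast, config = scan_config()) {
  m <- contrast_matrices(counts, contrast, config$pool_size,
                         substitutions_only = TRUE)
  if (nrow(m$a) < 50) {
    abort("the scan needs at least 50 usable loci to estimate beta")
  }
  fit <- bayescan_mcmc(
    m$a, m$n, config$prior_odds,
    as.integer(config$pilot_runs), as.integer(config$pilot_length),
    as.integer(config$burn_in), as.integer(config$iterations),
    as.integer(config$thin),
    1.0, -1.0, 1.8
  )
  converged <- fit$split_disagreement < 0.5
  if (!converged) {
    warn(sprintf(
      "split-chain beta disagreement %.2f exceeds tolerance; results emitted",
      fit$split_disagreement
    ))
  }
  fst <- pooled_fst(counts, contrast, config$pool_size)
  contrast_label <- contrast$label
  contrast_line <- contrast$line
  res <- m$loci %>%
    dplyr::left_join(fst, by = c("chrom", "pos", "skipped")) %>%
    dplyr::mutate(contrast = contrast_label, line = contrast_line,
                  post_prob = NA_real_, alpha = NA_real_, q = NA_real_)
  keep <- !res$skipped
  res$post_prob[keep] <- fit$post_prob
  res$alpha[keep] <- fit$alpha_mean
  res$q[keep] <- q_values(fit$post_prob)
  structure(list(
    result = res %>% dplyr::select("chrom", "pos", "contrast", "line",
                                   "fst", "post_prob", "alpha", "q",
                                   "skipped"),
    beta = fit$beta_mean,
    split_disagreement = fit$split_disagreement,
    converged = converged,
    kept_samples = fit$kept_samples,
    config = config
  ), class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf(
    "<fst_scan: %s, line %s; %d loci, %d with q < %.2f; beta = %s>\n",
    x$result$contrast[1], x$result$line[1], nrow(x$result),
    sum(x$result$q < x$config$q_threshold, na.rm = TRUE),
    x$config$q_threshold,
    paste(sprintf("%.2f", x$beta), collapse = ", ")
  ))
  invisible(x)
}

#' Tidy a Bayesian scan fit
#'
#' @param x An `fst_scan` object.
#' @param ... Unused.
#' @return `tidy()`: the per-locus result tibble. `glance()`: a one-row
#'   summary (loci scanned, significant count, beta range, convergence).
#' @export
#' @importFrom generics tidy
tidy.fst_scan <- function(x, ...) x$result

#' @rdname tidy.fst_scan
#' @export
#' @importFrom generics glance
glance.fst_scan <- function(x, ...) {
  tibble::tibble(
    contrast = x$result$contrast[1],
    line = x$result$line[1],
    n_loci = nrow(x$result),
    n_skipped = sum(x$result$skipped),
    n_significant = sum(x$result$q < x$config$q_threshold, na.rm = TRUE),
    beta_min = min(x$beta), beta_max = max(x$beta),
    split_disagreement = x$split_disagreement,
    converged = x$converged,
    kept_samples = x$kept_samples
  )
}
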