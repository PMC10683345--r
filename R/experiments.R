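# Scripted simulation experiments: type-I error and power of the test under
# the four familial-dependence generators, plus multiple-testing summaries.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.99).
#' @return named vector `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.99) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Configuration of a simulation experiment
#'
#' Bundles the generating model and test options for [run_type1_experiment()]
#' and [run_power_experiment()]. Defaults follow the reference simulation
#' design: 120 families (40 trios, 40 quartets, 40 three-generation octets),
#' 20 SNPs with MAF drawn from Uniform(0.003, 0.01) and adjacent-SNP
#' `d2 = 0.16`, covariate effects `gamma = (-2, 1, 1)`, and 5 causal variants
#' under the alternative.
#'
#' @param setting `"copula_gaussian"`, `"glmm"`, `"copula_t"` or
#'   `"copula_chisq"`.
#' @param h2 generating polygenic heritability.
#' @param tau variance component (0 = null).
#' @param n_replicates number of replicate data sets.
#' @param seed master seed; per-replicate streams are drawn from it so each
#'   replicate is independently reproducible.
#' @param kernels character vector of kernels to test per replicate.
#' @param alpha nominal levels at which rejection rates are reported.
#' @param ped pedigree (default [default_pedigree_set()]).
#' @param region genotype [region_spec()].
#' @param gamma covariate coefficients (intercept first).
#' @param n_causal number of causal variants under the alternative.
#' @param df,a Student-t df / chi-square noncentrality for the
#'   mis-specification settings.
#' @param h2_fit `"auto"` or a fixed value handed to [nrvat_test()].
#' @param weights weight scheme handed to [nrvat_test()].
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(setting = c("copula_gaussian", "glmm",
                                          "copula_t", "copula_chisq"),
                              h2 = 0.5, tau = 0, n_replicates = 2000,
                              seed = 1, kernels = "linear",
                              alpha = c(0.05, 0.01),
                              ped = default_pedigree_set(),
                              region = region_spec(),
                              gamma = c(-2, 1, 1), n_causal = 5,
                              df = 3, a = 1, h2_fit = "auto",
                              weights = "beta") {
  setting <- match.arg(setting)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha levels must lie in (0, 1)")
  structure(list(setting = setting, h2 = h2, tau = tau,
                 n_replicates = as.integer(n_replicates), seed = seed,
                 kernels = kernels, alpha = alpha, ped = ped, region = region,
                 gamma = gamma, n_causal = n_causal, df = df, a = a,
                 h2_fit = h2_fit, weights = weights),
            class = "experiment_config")
}

# One simulated data set under a config (beta may be nonzero).
simulate_dataset <- function(cfg, psi_blocks, beta = NULL) {
  G <- simulate_genotypes(cfg$ped, cfg$region)
  X <- simulate_covariates(cfg$ped)
  Y <- switch(cfg$setting,
    copula_gaussian = simulate_setting1(cfg$ped, X, G, cfg$gamma, beta,
                                        cfg$h2, psi_blocks),
    glmm = simulate_glmm(cfg$ped, X, G, cfg$gamma, beta, cfg$h2, psi_blocks),
    copula_t = simulate_t_copula(cfg$ped, X, G, cfg$gamma, beta, cfg$h2,
                                 cfg$df, psi_blocks),
    copula_chisq = simulate_chisq_copula(cfg$ped, X, G, cfg$gamma, beta,
                                         cfg$h2, cfg$a, psi_blocks))
  list(Y = Y, X = X, G = G)
}

# One replicate's p-values for several kernels, sharing the null fit, the
# heritability estimate, Omega and its factorization across kernels.
test_all_kernels <- function(Y, X, G, ped, kernels, weights, h2_fit,
                             psi_blocks) {
  founder_sel <- ped$founder
  maf <- sample_maf(G, founder_sel)
  poly <- maf > 0
  G <- G[, poly, drop = FALSE]
  maf <- pmax(pmin(maf[poly], 1 - maf[poly]), 1e-12)
  w <- if (is.numeric(weights)) weights[poly] else {
    maf_weights(maf, match.arg(weights, c("beta", "flat")))
  }
  fit <- fit_null_logistic(Y, X, ped$fid)
  h2_hat <- if (identical(h2_fit, "auto")) {
    estimate_h2(Y, fit$mu_hat, ped, psi_blocks)$h2_hat
  } else h2_fit
  sig <- sigma_blocks(fit$mu_hat, ped, psi_blocks, h2_hat)
  Omega <- build_omega(fit, sig, X, ped)
  prep <- prep_omega(Omega)
  res <- Y - fit$mu_hat
  p <- vapply(kernels, function(kn) {
    K <- kernel_matrix(G, w, kn)
    Q <- drop(crossprod(res, K %*% res))
    pvalue_mixture_chisq(Q, prep, K)$p_value
  }, numeric(1))
  names(p) <- kernels
  p
}

run_experiment <- function(cfg, alternative) {
  psi_blocks <- relatedness_blocks(cfg$ped)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, cfg$n_replicates)
  p_mat <- matrix(NA_real_, cfg$n_replicates, length(cfg$kernels),
                  dimnames = list(NULL, cfg$kernels))
  for (b in seq_len(cfg$n_replicates)) {
    set.seed(rep_seeds[b])
    beta <- NULL
    if (alternative) {
      spec <- resolve_region(cfg$region)
      causal <- sample.int(spec$r, cfg$n_causal)
      w_gen <- maf_weights(spec$maf, "beta")
      beta <- draw_beta(spec$r, cfg$tau, w_gen, causal)
      dat_region <- spec
    } else {
      dat_region <- cfg$region
    }
    cfg_b <- cfg
    cfg_b$region <- dat_region
    dat <- simulate_dataset(cfg_b, psi_blocks, beta)
    p_mat[b, ] <- tryCatch(
      test_all_kernels(dat$Y, dat$X, dat$G, cfg$ped, cfg$kernels,
                       cfg$weights, cfg$h2_fit, psi_blocks),
      error = function(e) rep(NA_real_, length(cfg$kernels)))
  }
  rates <- do.call(rbind, lapply(cfg$kernels, function(kn) {
    do.call(rbind, lapply(cfg$alpha, function(al) {
      ok <- !is.na(p_mat[, kn])
      ci <- wilson_ci(sum(p_mat[ok, kn] <= al), sum(ok))
      data.frame(kernel = kn, alpha = al, n = sum(ok),
                 rate = ci[["estimate"]], lower = ci[["lower"]],
                 upper = ci[["upper"]])
    }))
  }))
  rownames(rates) <- NULL
  structure(list(config = cfg, p_values = p_mat, rates = rates,
                 alternative = alternative,
                 manifest = list(seed = cfg$seed,
                                 n_replicates = cfg$n_replicates,
                                 setting = cfg$setting, h2 = cfg$h2,
                                 tau = cfg$tau,
                                 timestamp = format(Sys.time(), tz = "UTC"))),
            class = "experiment_report")
}

#' Empirical type-I error experiment
#'
#' Simulates `n_replicates` null data sets (`beta = 0`) under the configured
#' dependence model, runs the full test per kernel and reports empirical
#' rejection rates at each nominal level with Wilson 99% intervals.
#'
#' @param cfg an [experiment_config()] (with `tau` ignored).
#' @return `experiment_report`: list with `p_values` (replicates x kernels),
#'   `rates` (data frame), and a run `manifest`.
#' @export
run_type1_experiment <- function(cfg) {
  cfg$tau <- 0
  run_experiment(cfg, alternative = FALSE)
}

#' Empirical power experiment
#'
#' As [run_type1_experiment()], but each replicate redraws `n_causal` causal
#' variants and their effects `beta ~ N(0, tau * w)`.
#'
#' @param cfg an [experiment_config()] with `tau > 0`.
#' @return an `experiment_report`.
#' @export
run_power_experiment <- function(cfg) {
  if (cfg$tau <= 0) stop("power experiment requires tau > 0 (use run_type1_experiment for tau = 0)")
  run_experiment(cfg, alternative = TRUE)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s, h2 = %g, tau = %g, B = %d\n",
              x$config$setting, x$config$h2, x$config$tau,
              x$config$n_replicates))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Expected vs observed quantiles for a QQ-plot of p-values
#'
#' @param p vector of p-values.
#' @return data frame with `expected` and `observed` `-log10` p columns.
#' @export
qq_plot_data <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}

#' Bonferroni multiple-testing summary
#'
#' Flags variant sets significant after Bonferroni correction, either per trait
#' (`m` = tests within each trait) or overall (`m` = pooled test count across
#' traits).
#'
#' @param p_table data frame with columns `trait`, `set_id`, `p_value`.
#' @param alpha nominal family-wise level (default 0.05).
#' @param scheme `"bonferroni_per_trait"` or `"bonferroni_overall"`.
#' @return list with `threshold` (named per trait, or scalar for overall),
#'   `m`, and `significant` (subset of `p_table` passing).
#' @export
summarize_multiple_testing <- function(p_table, alpha = 0.05,
                                       scheme = c("bonferroni_per_trait",
                                                  "bonferroni_overall")) {
  scheme <- match.arg(scheme)
  if (nrow(p_table) == 0) stop("empty p-value table")
  if (scheme == "bonferroni_overall") {
    m <- nrow(p_table)
    thr <- alpha / m
    sig <- p_table[p_table$p_value <= thr, , drop = FALSE]
    list(threshold = thr, m = m, significant = sig)
  } else {
    m <- table(p_table$trait)
    thr <- alpha / as.numeric(m)
    names(thr) <- names(m)
    sig <- p_table[p_table$p_value <= thr[as.character(p_table$trait)], ,
                   drop = FALSE]
    list(threshold = thr, m = as.numeric(m), significant = sig)
  }
}
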