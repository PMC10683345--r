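# Binary phenotype generators: the Gaussian-copula model the test assumes,
# plus the GLMM, Student-t-copula and chi-square-copula alternatives used to
# probe robustness to mis-specified familial dependence.

# One multivariate-normal draw with covariance U'U (U = chol upper factor).
.rmvn1 <- function(U) drop(crossprod(U, stats::rnorm(nrow(U))))

#' Simulate the default covariate design
#'
#' An intercept column, a continuous covariate `X1 ~ Uniform[0, 1]` and a
#' binary covariate `X2 ~ Bernoulli(0.2)`, independent across individuals.
#'
#' @param ped a [pedigree()] (or anything with `nrow()`), fixing N.
#' @return N x 3 matrix with columns `(Intercept)`, `X1`, `X2`.
#' @export
simulate_covariates <- function(ped) {
  n <- nrow(ped)
  cbind(`(Intercept)` = rep(1, n),
        X1 = stats::runif(n),
        X2 = stats::rbinom(n, 1, 0.2))
}

#' Draw variant effects under the variance-component alternative
#'
#' Effects are zero except on `causal` variants, where they are independent
#' `Normal(0, tau * w_l)`; `tau = 0` gives the null.
#'
#' @param r number of variants.
#' @param tau variance-component scalar (>= 0).
#' @param weights positive per-variant weights `w_l` (length r), giving
#'   causal-effect variances `tau * w_l`.
#' @param causal indices of causal variants (default: all).
#' @return effect vector beta of length r.
#' @export
draw_beta <- function(r, tau, weights = rep(1, r), causal = seq_len(r)) {
  if (tau < 0) stop("tau must be >= 0")
  if (length(weights) != r) stop("weights must have length r")
  beta <- numeric(r)
  if (tau > 0 && length(causal)) {
    beta[causal] <- stats::rnorm(length(causal), 0,
                                 sqrt(tau * weights[causal]))
  }
  beta
}

# Shared: marginal success probabilities from the logistic model.
marginal_mu <- function(X, G, gamma, beta) {
  eta <- drop(X %*% gamma)
  if (!is.null(G) && !is.null(beta) && any(beta != 0)) {
    eta <- eta + drop(G %*% beta)
  }
  stats::plogis(eta)
}

# Family index helper: list of global row indices per family.
family_index <- function(ped) {
  split(seq_len(nrow(ped)), factor(ped$fid, levels = unique(ped$fid)))
}

#' Gaussian-copula binary phenotypes
#'
#' The generating model of the test itself: marginal means
#' `mu = logit^-1(X gamma + G beta)`; per family a latent vector
#' `Z ~ N(0, Gamma_i)` with `Gamma_i = h2 Psi_i + (1 - h2) I`, and
#' `Y_ij = 1{Z_ij <= qnorm(mu_ij)}`. The copula leaves the marginal means
#' untouched for every `h2`.
#'
#' @param ped a [pedigree()].
#' @param X covariate matrix (first column ones).
#' @param G dosage matrix or `NULL`.
#' @param gamma covariate coefficients.
#' @param beta variant effects (or `NULL`).
#' @param h2 polygenic heritability in `[0, 1)`.
#' @param psi_blocks optional precomputed [relatedness_blocks()] (saves time in
#'   replicate loops).
#' @return integer 0/1 phenotype vector of length N.
#' @export
simulate_setting1 <- function(ped, X, G, gamma, beta = NULL, h2 = 0,
                              psi_blocks = NULL) {
  mu <- marginal_mu(X, G, gamma, beta)
  thr <- stats::qnorm(mu)
  if (is.null(psi_blocks)) psi_blocks <- relatedness_blocks(ped)
  y <- integer(length(mu))
  fam <- family_index(ped)
  for (i in seq_along(fam)) {
    rows <- fam[[i]]
    z <- if (h2 == 0) stats::rnorm(length(rows))
         else .rmvn1(chol(copula_correlation(psi_blocks[[i]], h2)))
    y[rows] <- as.integer(z <= thr[rows])
  }
  y
}

#' GLMM binary phenotypes (conditional-model alternative)
#'
#' `logit(mu_i) = X_i gamma + G_i beta + b_i` with family random effects
#' `b_i ~ N(0, h2 Psi_i)`; outcomes conditionally independent Bernoulli. Unlike
#' the copula generators this changes the marginal means when `h2 > 0`.
#'
#' @inheritParams simulate_setting1
#' @return integer 0/1 phenotype vector.
#' @export
simulate_glmm <- function(ped, X, G, gamma, beta = NULL, h2 = 0,
                          psi_blocks = NULL) {
  eta <- drop(X %*% gamma)
  if (!is.null(G) && !is.null(beta) && any(beta != 0)) eta <- eta + drop(G %*% beta)
  if (h2 > 0) {
    if (is.null(psi_blocks)) psi_blocks <- relatedness_blocks(ped)
    fam <- family_index(ped)
    for (i in seq_along(fam)) {
      eta[fam[[i]]] <- eta[fam[[i]]] + sqrt(h2) * .rmvn1(chol(psi_blocks[[i]]))
    }
  }
  stats::rbinom(length(eta), 1, stats::plogis(eta))
}

#' Student-t-copula binary phenotypes (elliptic mis-specification)
#'
#' The latent vector follows a multivariate Student t with `df` degrees of
#' freedom and correlation matrix `Gamma_i` (Gaussian scale-mixture
#' construction: correlated normal divided by `sqrt(chisq_df / df)`), and is
#' thresholded at `qnorm(mu)` exactly as in the Gaussian-copula generator. The
#' heavy-tailed margin makes the realized marginal means
#' `pt(qnorm(mu), df)`, not `mu` - deliberate mis-specification. Set
#' `correct_margins = TRUE` to threshold at `qt(mu, df)` instead, giving a pure
#' t-copula with preserved margins.
#'
#' @inheritParams simulate_setting1
#' @param df degrees of freedom (> 0, default 3).
#' @param correct_margins apply the margin-preserving threshold (default FALSE).
#' @return integer 0/1 phenotype vector.
#' @export
simulate_t_copula <- function(ped, X, G, gamma, beta = NULL, h2 = 0, df = 3,
                              psi_blocks = NULL, correct_margins = FALSE) {
  if (df <= 0) stop("df must be > 0")
  mu <- marginal_mu(X, G, gamma, beta)
  thr <- if (correct_margins) stats::qt(mu, df) else stats::qnorm(mu)
  if (is.null(psi_blocks)) psi_blocks <- relatedness_blocks(ped)
  y <- integer(length(mu))
  fam <- family_index(ped)
  for (i in seq_along(fam)) {
    rows <- fam[[i]]
    z <- if (h2 == 0) stats::rnorm(length(rows))
         else .rmvn1(chol(copula_correlation(psi_blocks[[i]], h2)))
    z <- z / sqrt(stats::rchisq(1, df) / df)
    y[rows] <- as.integer(z <= thr[rows])
  }
  y
}

#' Chi-square-copula transform
#'
#' Maps a standard normal variate to a uniform via the distribution function
#' of `(z + a)^2` (a noncentral chi-square with noncentrality `a^2`):
#' `U = sign(z + a) * (pnorm(z + 2a) + pnorm(z) - 1)`, with `sign(0) = 0` and
#' `U` clipped to `[1e-12, 1 - 1e-12]` so `qnorm(U)` stays finite.
#'
#' @param z numeric vector.
#' @param a noncentrality parameter (>= 0).
#' @return vector of clipped uniforms.
#' @export
chisq_copula_transform <- function(z, a = 1) {
  if (a < 0) stop("a must be >= 0")
  u <- sign(z + a) * (stats::pnorm(z + 2 * a) + stats::pnorm(z) - 1)
  pmin(1 - 1e-12, pmax(1e-12, u))
}

#' Chi-square-copula binary phenotypes (asymmetric mis-specification)
#'
#' Per family, `Ztilde ~ N(0, Gamma_i)` is pushed through
#' [chisq_copula_transform()] and back through `qnorm`, yielding a latent
#' vector with standard-normal margins but a chi-square copula; thresholding
#' at `qnorm(mu)` then preserves the marginal means while distorting the
#' dependence structure.
#'
#' @inheritParams simulate_setting1
#' @param a noncentrality parameter (default 1).
#' @return integer 0/1 phenotype vector.
#' @export
simulate_chisq_copula <- function(ped, X, G, gamma, beta = NULL, h2 = 0, a = 1,
                                  psi_blocks = NULL) {
  mu <- marginal_mu(X, G, gamma, beta)
  thr <- stats::qnorm(mu)
  if (is.null(psi_blocks)) psi_blocks <- relatedness_blocks(ped)
  y <- integer(length(mu))
  fam <- family_index(ped)
  for (i in seq_along(fam)) {
    rows <- fam[[i]]
    zt <- if (h2 == 0) stats::rnorm(length(rows))
          else .rmvn1(chol(copula_correlation(psi_blocks[[i]], h2)))
    z <- stats::qnorm(chisq_copula_transform(zt, a))
    y[rows] <- as.integer(z <= thr[rows])
  }
  y
}

#' Mask subjects missing completely at random or at random given covariates
#'
#' MCAR masks each subject independently with probability `p`; MAR uses a
#' logit-linear probability in the covariates,
#' `logit(p_j) = theta_0 + theta' X_j`, with `theta_0` solved so the average
#' masking rate is `p` and default slopes `(1, 1)` on `(X1, X2)`. Masked
#' subjects have `Y` set to `NA`; downstream analysis removes them listwise.
#'
#' @param Y phenotype vector.
#' @param X covariate matrix (intercept first column).
#' @param p target masking probability in `[0, 1)`.
#' @param mechanism `"mcar"` or `"mar"`.
#' @param slopes MAR coefficients on the non-intercept covariates.
#' @return `Y` with masked entries set to `NA`.
#' @export
apply_missingness <- function(Y, X, p, mechanism = c("mcar", "mar"),
                              slopes = rep(1, ncol(X) - 1)) {
  mechanism <- match.arg(mechanism)
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  if (p == 0) return(Y)
  n <- length(Y)
  if (mechanism == "mcar") {
    drop <- stats::rbinom(n, 1, p) == 1
  } else {
    lin <- drop(X[, -1, drop = FALSE] %*% slopes)
    f <- function(t0) mean(stats::plogis(t0 + lin)) - p
    t0 <- stats::uniroot(f, c(-30, 30))$root
    drop <- stats::rbinom(n, 1, stats::plogis(t0 + lin)) == 1
  }
  Y[drop] <- NA
  Y
}
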