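# The NRVAT test: marginal logistic null model under working independence,
# polygenic heritability by pairwise composite likelihood on the Gaussian
# copula, sandwich residual covariance Omega, quadratic score statistic Q and
# its mixture-of-chi-square p-value.

#' Fit the null logistic model under working independence
#'
#' Maximizes the independence log-likelihood of `logit(mu) = X gamma` by
#' iteratively reweighted least squares, then polishes with Newton steps until
#' the score norm is below `1e-8`. Returns the pieces the sandwich covariance
#' needs: fitted means, `Delta = diag(mu (1 - mu))` (as a vector), the bread
#' `A = (1/I) sum_i X_i' Delta_i X_i` and the per-family scores
#' `S_i = X_i' (Y_i - mu_i)`.
#'
#' @param Y binary 0/1 phenotype vector (no missing values).
#' @param X N x (s+1) covariate matrix, full column rank, intercept included.
#' @param fid family identifier vector of length N (order defining families).
#' @return object of class `nrvat_null`: list with `gamma_hat`, `mu_hat`,
#'   `delta` (vector mu(1-mu)), `A_hat`, `scores` (I x (s+1) matrix of S_i),
#'   `n_families`, `converged`.
#' @export
fit_null_logistic <- function(Y, X, fid) {
  if (anyNA(Y) || anyNA(X)) stop("missing values: apply listwise deletion first")
  if (!all(Y %in% c(0, 1))) stop("Y must be binary 0/1")
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  fit <- stats::glm.fit(X, Y, family = stats::binomial(),
                        control = list(epsilon = 1e-12, maxit = 100))
  gamma_hat <- fit$coefficients
  # Newton polish to score norm < 1e-8
  for (it in 1:25) {
    mu <- drop(stats::plogis(X %*% gamma_hat))
    g <- drop(crossprod(X, Y - mu))
    if (sqrt(sum(g^2)) < 1e-8) break
    H <- crossprod(X, X * (mu * (1 - mu)))
    gamma_hat <- gamma_hat + solve(H, g)
  }
  mu <- drop(stats::plogis(X %*% gamma_hat))
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    stop("fitted probabilities numerically 0 or 1: quasi-complete separation; ",
         "remove or recode the offending covariate")
  }
  g <- drop(crossprod(X, Y - mu))
  converged <- sqrt(sum(g^2)) < 1e-8
  if (!converged) warning("null model score norm ", format(sqrt(sum(g^2))),
                          " after Newton polish")
  fam <- split(seq_along(Y), factor(fid, levels = unique(fid)))
  I <- length(fam)
  delta <- mu * (1 - mu)
  A_hat <- crossprod(X, X * delta) / I
  scores <- t(vapply(fam, function(rows) {
    drop(crossprod(X[rows, , drop = FALSE], Y[rows] - mu[rows]))
  }, numeric(ncol(X))))
  structure(list(gamma_hat = gamma_hat, mu_hat = mu, delta = delta,
                 A_hat = A_hat, scores = scores, n_families = I,
                 fid = fid, converged = converged),
            class = "nrvat_null")
}

#' Joint success probability of a correlated binary pair
#'
#' `P(Y_j = 1, Y_k = 1)` under the Gaussian copula with marginal means
#' `mu_j`, `mu_k` and latent correlation `rho`:
#' `Phi2(qnorm(mu_j), qnorm(mu_k); rho)`. Vectorized.
#'
#' @param mu_j,mu_k marginal means in (0, 1).
#' @param rho latent correlation(s), `|rho| < 1`.
#' @return joint probabilities.
#' @export
pair_prob <- function(mu_j, mu_k, rho) {
  if (any(mu_j <= 0 | mu_j >= 1 | mu_k <= 0 | mu_k >= 1)) {
    stop("marginal means must lie strictly in (0, 1)")
  }
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  pbvnorm(stats::qnorm(mu_j), stats::qnorm(mu_k), rho)
}

# Cached combn(n, 2) - called for every family in every replicate.
.combn2_cache <- new.env(parent = emptyenv())
combn2 <- function(n) {
  key <- as.character(n)
  if (is.null(.combn2_cache[[key]])) {
    .combn2_cache[[key]] <- utils::combn(n, 2)
  }
  .combn2_cache[[key]]
}

# Within-family relative-pair index for the composite likelihood and Sigma:
# unordered pairs (j < k) with global row indices and Psi entries.
relative_pairs <- function(ped, psi_blocks) {
  fam <- family_index(ped)
  jj <- kk <- integer(0)
  ps <- numeric(0)
  for (i in seq_along(fam)) {
    rows <- fam[[i]]
    ni <- length(rows)
    if (ni < 2) next
    cmb <- combn2(ni)
    jj <- c(jj, rows[cmb[1, ]])
    kk <- c(kk, rows[cmb[2, ]])
    ps <- c(ps, psi_blocks[[i]][cbind(cmb[1, ], cmb[2, ])])
  }
  list(j = jj, k = kk, psi = ps)
}

#' Estimate polygenic heritability by pairwise composite likelihood
#'
#' Maximizes, under the null model, the sum over within-family relative pairs
#' of bivariate log-likelihood contributions
#' `log P(Y_j = y_j, Y_k = y_k)`, where the four cell probabilities come from
#' the Gaussian copula with latent pair correlation `h2 * Psi_jk`. The double
#' sum over ordered pairs in the defining formula duplicates each pair; the
#' factor 2 does not move the argmax, so unordered pairs are used. Pairs with
#' `Psi_jk = 0` contribute a constant and are skipped.
#'
#' @param Y binary phenotype vector.
#' @param mu_hat fitted null means.
#' @param ped a [pedigree()] aligned to `Y`.
#' @param psi_blocks optional precomputed [relatedness_blocks()].
#' @param tol optimizer tolerance on h2 (default 1e-4).
#' @return list with `h2_hat`, `loglik`, `n_pairs`.
#' @export
estimate_h2 <- function(Y, mu_hat, ped, psi_blocks = NULL, tol = 1e-4) {
  if (is.null(psi_blocks)) psi_blocks <- relatedness_blocks(ped)
  pr <- relative_pairs(ped, psi_blocks)
  rel <- pr$psi > 0
  if (!any(rel)) {
    if (length(pr$psi) == 0) {
      stop("no family with 2+ members: h2 cannot be estimated, supply it explicitly")
    }
    warning("no relative pair with Psi > 0: pairwise likelihood is flat in h2; returning 0")
    return(list(h2_hat = 0, loglik = NA_real_, n_pairs = 0L))
  }
  j <- pr$j[rel]; k <- pr$k[rel]; psi <- pr$psi[rel]
  mj <- mu_hat[j]; mk <- mu_hat[k]
  yj <- Y[j]; yk <- Y[k]
  cell <- 2L * yj + yk  # 3: (1,1), 2: (1,0), 1: (0,1), 0: (0,0)
  obj <- function(h2) {
    p11 <- pair_prob(mj, mk, h2 * psi)
    p <- numeric(length(p11))
    p[cell == 3L] <- p11[cell == 3L]
    p[cell == 2L] <- (mj - p11)[cell == 2L]
    p[cell == 1L] <- (mk - p11)[cell == 1L]
    p[cell == 0L] <- (1 - mj - mk + p11)[cell == 0L]
    sum(log(pmax(p, 1e-300)))
  }
  opt <- stats::optimize(obj, c(0, 1 - 1e-6), maximum = TRUE, tol = tol)
  h2_hat <- opt$maximum
  # optimize() never returns the exact boundary; snap when the edge is better
  if (obj(0) >= opt$objective) h2_hat <- 0
  list(h2_hat = h2_hat, loglik = obj(h2_hat), n_pairs = sum(rel))
}

#' Residual covariance block of one family
#'
#' `Sigma_i` under the Gaussian copula: diagonal `mu (1 - mu)`; off-diagonal
#' `(j, k)` entries `P(Y_j = 1, Y_k = 1) - mu_j mu_k` with latent correlation
#' `Gamma_i[j, k]`.
#'
#' @param mu_i vector of the family's fitted means.
#' @param gamma_i the family's copula correlation matrix ([copula_correlation()]).
#' @return symmetric ni x ni covariance matrix.
#' @export
sigma_block <- function(mu_i, gamma_i) {
  ni <- length(mu_i)
  S <- diag(mu_i * (1 - mu_i), ni)
  if (ni > 1) {
    cmb <- combn2(ni)
    rho <- gamma_i[cbind(cmb[1, ], cmb[2, ])]
    v <- pair_prob(mu_i[cmb[1, ]], mu_i[cmb[2, ]], rho) -
      mu_i[cmb[1, ]] * mu_i[cmb[2, ]]
    S[cbind(cmb[1, ], cmb[2, ])] <- v
    S[cbind(cmb[2, ], cmb[1, ])] <- v
  }
  S
}

# All Sigma blocks for a pedigree at a given h2.
sigma_blocks <- function(mu_hat, ped, psi_blocks, h2) {
  fam <- family_index(ped)
  lapply(seq_along(fam), function(i) {
    sigma_block(mu_hat[fam[[i]]],
                copula_correlation(psi_blocks[[i]], h2))
  })
}

#' Sandwich covariance of the null residuals
#'
#' Assembles `Omega = Var(Y - mu_hat)`, accounting for the estimation of
#' `gamma`: with `P_i = Delta_i X_i` and `R_i = Sigma_i X_i`,
#' `Omega_{ii'} = 1{i = i'} Sigma_i - (1/I) (P_i A^-1 R_{i'}' + R_i A^-1 P_{i'}'
#' - P_i A^-1 B A^-1 P_{i'}')`, symmetrized as `(Omega + Omega') / 2`. The
#' bread is `A_hat` from the fit; `B` is either model-based,
#' `(1/I) sum_i X_i' Sigma_i X_i` (default: uses the fitted copula, smoother at
#' moderate family counts), or empirical, `(1/I) sum_i S_i S_i'`.
#'
#' @param fit a [fit_null_logistic()] result.
#' @param sig_blocks list of per-family `Sigma_i` ([sigma_block()]).
#' @param X covariate matrix.
#' @param ped the [pedigree()].
#' @param b_mode `"model"` or `"empirical"`.
#' @return N x N symmetric matrix.
#' @export
build_omega <- function(fit, sig_blocks, X, ped, b_mode = c("model", "empirical")) {
  b_mode <- match.arg(b_mode)
  fam <- family_index(ped)
  I <- length(fam)
  A_inv <- solve(fit$A_hat)
  P <- X * fit$delta                      # rows Delta_i X_i stacked
  R <- matrix(0, nrow(X), ncol(X))        # rows Sigma_i X_i stacked
  for (i in seq_along(fam)) {
    rows <- fam[[i]]
    R[rows, ] <- sig_blocks[[i]] %*% X[rows, , drop = FALSE]
  }
  B <- if (b_mode == "empirical") {
    crossprod(fit$scores) / I
  } else {
    crossprod(X, R) / I
  }
  Omega <- block_diagonal(sig_blocks)
  PAinv <- P %*% A_inv
  Omega <- Omega - (tcrossprod(PAinv, R) + tcrossprod(R %*% A_inv, P) -
                      PAinv %*% B %*% t(PAinv)) / I
  (Omega + t(Omega)) / 2
}

#' Quadratic score statistic
#'
#' `Q = (Y - mu_hat)' K (Y - mu_hat)`. The score derivative of the
#' variance-component likelihood at `tau = 0` also carries a centering term
#' `tr(K Delta)` whose variability is negligible; it is returned as a
#' diagnostic only and never enters the p-value.
#'
#' @param Y binary phenotype vector.
#' @param mu_hat fitted null means.
#' @param K kernel matrix ([kernel_matrix()]).
#' @return list with `Q` and `trace_K_delta`.
#' @export
score_statistic <- function(Y, mu_hat, K) {
  res <- Y - mu_hat
  list(Q = drop(crossprod(res, K %*% res)),
       trace_K_delta = sum(diag(K) * mu_hat * (1 - mu_hat)))
}

# Factorization of Omega for the null spectrum: Cholesky when positive
# definite, otherwise eigendecomposition with negative eigenvalues clipped at
# 0 (clip count/mass recorded; warning when the clipped mass is material).
# `half` is any matrix H with H'H = Omega_+, so eig(H K H') = eig(K Omega_+)
# = eig(Omega_+^{1/2} K Omega_+^{1/2}).
prep_omega <- function(Omega) {
  Omega <- (Omega + t(Omega)) / 2
  U <- tryCatch(chol(Omega), error = function(e) NULL)
  if (!is.null(U)) {
    out <- list(half = U, n_clipped = 0L, clip_mass = 0)
  } else {
    eo <- eigen(Omega, symmetric = TRUE)
    lam <- eo$values
    n_clipped <- sum(lam < 0)
    clip_mass <- -sum(lam[lam < 0])
    if (clip_mass > 1e-3 * sum(abs(lam))) {
      warning("Omega clipped eigenvalue mass ", format(clip_mass),
              " exceeds 1e-3 of its trace")
    }
    out <- list(half = sqrt(pmax(lam, 0)) * t(eo$vectors),
                n_clipped = n_clipped, clip_mass = clip_mass)
  }
  structure(out, class = "nrvat_omega_prep")
}

#' Mixture-of-chi-square p-value for the score statistic
#'
#' The null law of `Q` is `sum_n theta_n chisq_1`, with `theta_n` the
#' eigenvalues of `Omega^{1/2} K Omega^{1/2}`. `Omega` may be numerically
#' indefinite at finite family counts; negative eigenvalues are clipped at 0
#' before the square root (clip count and mass reported, with a warning when
#' the clipped mass exceeds `1e-3 * trace`). The spectrum is computed from a
#' factor `H` with `H'H = Omega_+` (Cholesky when positive definite, clipped
#' eigen square root otherwise): `eig(H K H')` equals
#' `eig(Omega_+^{1/2} K Omega_+^{1/2})`, and when `K` carries a factor `C`
#' (`K = C C'`, e.g. the linear kernel) the equal-spectrum r x r matrix
#' `C' Omega_+ C` is used instead. Eigenvalues below `1e-10 * max(theta)` are
#' dropped.
#' The tail probability uses exact characteristic-function inversion
#' ([imhof_tail()]) with the [liu_tail()] moment-matching fallback; the
#' method used is reported.
#'
#' @param Q observed statistic.
#' @param Omega residual covariance ([build_omega()]).
#' @param K kernel matrix.
#' @return list with `p_value`, `theta` (retained spectrum), `method`
#'   (`"imhof"` or `"liu"`), `n_clipped`, `clip_mass`.
#' @export
pvalue_mixture_chisq <- function(Q, Omega, K) {
  prep <- if (inherits(Omega, "nrvat_omega_prep")) Omega else prep_omega(Omega)
  Cfac <- attr(K, "factor")
  theta <- if (!is.null(Cfac)) {
    V <- prep$half %*% Cfac                      # (H C)'(H C) = C' Omega_+ C
    eigen(crossprod(V), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(prep$half %*% K %*% t(prep$half), symmetric = TRUE,
          only.values = TRUE)$values
  }
  n_clipped <- prep$n_clipped
  clip_mass <- prep$clip_mass
  theta <- theta[theta > 1e-10 * max(0, max(theta))]
  if (length(theta) == 0) {
    stop("degenerate test: all eigenvalues of the null spectrum are zero ",
         "(e.g. monomorphic region)")
  }
  tail <- quadform_tail(Q, theta)
  list(p_value = tail$p, theta = theta, method = tail$method,
       n_clipped = n_clipped, clip_mass = clip_mass)
}

#' Copula-based variant-set association test
#'
#' End-to-end test of association between a variant set and a binary trait in
#' families: listwise deletion of subjects with any missing value, removal of
#' variants monomorphic among founders, null logistic fit, pairwise-likelihood
#' heritability (unless fixed), residual covariance `Omega`, kernel, statistic
#' `Q` and mixture-of-chi-square p-value.
#'
#' @param Y binary phenotype vector (NA allowed; removed listwise).
#' @param X covariate matrix including the intercept column.
#' @param G dosage matrix (0/1/2; NA removed listwise).
#' @param ped a [pedigree()] aligned to the rows of `Y`, `X`, `G`.
#' @param kernel kernel kind (see [kernel_matrix()]).
#' @param weights `"beta"` (Beta(1,25) MAF weights, default), `"flat"`, or a
#'   numeric vector of per-variant weights.
#' @param h2 `"auto"` (pairwise-likelihood estimate, default) or a fixed value
#'   in `[0, 1)`.
#' @param maf_source `"founders"` (default) or `"all"`: subjects used for the
#'   weight MAFs.
#' @param b_mode `B` estimator passed to [build_omega()].
#' @param set_id label carried into the result.
#' @param psi_blocks optional precomputed [relatedness_blocks()] for `ped`
#'   (avoids recomputing kinship in replicate loops).
#' @param ... further arguments to [kernel_matrix()] (`bandwidth`, `degree`).
#' @return object of class `nrvat_result`: list with `set_id`, `n_subjects`,
#'   `n_variants` (after filtering), `kernel`, `Q`, `p_value`, `h2_hat`,
#'   `theta`, `pvalue_method`, `trace_K_delta`, `n_clipped`, `dropped_variants`,
#'   `n_removed_subjects`, `gamma_hat`.
#' @export
nrvat_test <- function(Y, X, G, ped, kernel = "linear", weights = "beta",
                       h2 = "auto", maf_source = c("founders", "all"),
                       b_mode = "model", set_id = "set1", psi_blocks = NULL,
                       ...) {
  maf_source <- match.arg(maf_source)
  stopifnot(length(Y) == nrow(X), length(Y) == nrow(G), length(Y) == nrow(ped))
  if (length(unique(ped$fid)) < 30) {
    warning("fewer than 30 families: asymptotic p-values may be unreliable")
  }
  psi_blocks_full <- if (is.null(psi_blocks)) relatedness_blocks(ped) else psi_blocks

  keep <- !is.na(Y) & stats::complete.cases(X) & stats::complete.cases(G)
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    # kinship is computed on the full families, then rows/cols subset, so
    # remaining relatives keep their relatedness through removed members
    fam <- family_index(ped)
    psi_blocks <- list()
    fam_keep <- vapply(seq_along(fam), function(i) any(keep[fam[[i]]]), logical(1))
    jj <- 0L
    for (i in seq_along(fam)) {
      if (!fam_keep[i]) next
      jj <- jj + 1L
      sel <- keep[fam[[i]]]
      psi_blocks[[jj]] <- psi_blocks_full[[i]][sel, sel, drop = FALSE]
    }
    Y <- Y[keep]; X <- X[keep, , drop = FALSE]; G <- G[keep, , drop = FALSE]
    ped <- structure(as.data.frame(ped)[keep, , drop = FALSE],
                     class = c("pedigree", "data.frame"))
  } else {
    psi_blocks <- psi_blocks_full
  }

  founder_sel <- if (maf_source == "founders") ped$founder else rep(TRUE, nrow(ped))
  maf <- sample_maf(G, founder_sel)
  poly <- maf > 0
  dropped <- colnames(G)[!poly]
  if (!any(poly)) stop("all variants are monomorphic among the MAF source subjects")
  G <- G[, poly, drop = FALSE]
  maf <- pmin(maf[poly], 1 - maf[poly])  # fold to minor-allele scale
  maf <- pmax(maf, 1e-12)

  w <- if (is.numeric(weights)) {
    maf_weights(maf, "custom", custom = weights[poly])
  } else {
    maf_weights(maf, match.arg(weights, c("beta", "flat")))
  }

  fit <- fit_null_logistic(Y, X, ped$fid)
  h2_hat <- if (identical(h2, "auto")) {
    estimate_h2(Y, fit$mu_hat, ped, psi_blocks)$h2_hat
  } else {
    if (!is.numeric(h2) || h2 < 0 || h2 >= 1) stop("fixed h2 must lie in [0, 1)")
    h2
  }
  sig <- sigma_blocks(fit$mu_hat, ped, psi_blocks, h2_hat)
  Omega <- build_omega(fit, sig, X, ped, b_mode)
  K <- kernel_matrix(G, w, kernel, ...)
  sc <- score_statistic(Y, fit$mu_hat, K)
  pv <- pvalue_mixture_chisq(sc$Q, Omega, K)

  structure(list(set_id = set_id, n_subjects = length(Y),
                 n_variants = ncol(G), kernel = kernel, Q = sc$Q,
                 p_value = pv$p_value, h2_hat = h2_hat, theta = pv$theta,
                 pvalue_method = pv$method, trace_K_delta = sc$trace_K_delta,
                 n_clipped = pv$n_clipped, dropped_variants = dropped,
                 n_removed_subjects = n_removed, gamma_hat = fit$gamma_hat),
            class = "nrvat_result")
}

#' @export
print.nrvat_result <- function(x, ...) {
  cat(sprintf("<nrvat_result> set %s: %d subjects, %d variants, %s kernel\n",
              x$set_id, x$n_subjects, x$n_variants, x$kernel))
  cat(sprintf("  Q = %.4g, p = %.4g (%s), h2_hat = %.3f\n",
              x$Q, x$p_value, x$pvalue_method, x$h2_hat))
  if (length(x$dropped_variants)) {
    cat("  dropped monomorphic:", paste(x$dropped_variants, collapse = ", "), "\n")
  }
  if (x$n_removed_subjects > 0) {
    cat("  removed (listwise):", x$n_removed_subjects, "subjects\n")
  }
  invisible(x)
}
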