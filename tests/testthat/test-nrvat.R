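test_that("null logistic fit recovers closed-form intercepts and rejects bad input", {
  fid <- as.character(1:8)
  X <- matrix(1, 8, 1)
  f <- fit_null_logistic(c(1, 1, 1, 1, 0, 0, 0, 0), X, fid)
  expect_equal(unname(f$gamma_hat), 0, tolerance = 1e-10)
  f2 <- fit_null_logistic(c(1, 1, 0, 0, 0, 0, 0, 0), X, fid)
  expect_equal(unname(f2$gamma_hat), log(1 / 3), tolerance = 1e-10)
  expect_true(f2$converged)
  expect_equal(drop(unname(f2$A_hat)), mean(f2$delta), tolerance = 1e-12)

  expect_error(fit_null_logistic(c(0, 1, NA, 0, 1, 0, 1, 0), X, fid), "missing")
  expect_error(fit_null_logistic(rep(0:1, 4), cbind(X, X), fid), "rank")
  # perfect separation (glm.fit itself also warns; the error is the contract)
  xs <- cbind(1, c(rep(0, 4), rep(1, 4)))
  suppressWarnings(
    expect_error(fit_null_logistic(c(0, 0, 0, 0, 1, 1, 1, 1), xs, fid),
                 "separation"))
})

test_that("null fit is consistent for the generating coefficients", {
  set.seed(901)
  ped <- default_pedigree_set()
  big <- do.call(rbind, lapply(1:10, function(k) {
    d <- as.data.frame(ped)
    d$fid <- paste0(d$fid, "_", k)
    d
  }))
  big <- pedigree(big$fid, big$iid, big$pat, big$mat, big$sex)  # N = 6000
  X <- simulate_covariates(big)
  Y <- simulate_setting1(big, X, NULL, c(-2, 1, 1), h2 = 0)
  f <- fit_null_logistic(Y, X, big$fid)
  se <- sqrt(diag(solve(crossprod(X, X * f$delta))))
  expect_true(all(abs(f$gamma_hat - c(-2, 1, 1)) < 3 * se))
})

test_that("pair_prob matches closed forms and a 1e7-draw Monte-Carlo orthant", {
  expect_equal(pair_prob(0.5, 0.5, 0), 0.25)
  expect_equal(pair_prob(0.5, 0.5, 1 - 1e-12), 0.5, tolerance = 1e-5)
  expect_equal(pair_prob(0.5, 0.5, 0.25), 0.25 + asin(0.25) / (2 * pi))
  set.seed(902)
  mc <- mc_orthant(stats::qnorm(0.3), stats::qnorm(0.6), 0.4, n = 1e7)
  p <- pair_prob(0.3, 0.6, 0.4)
  se <- sqrt(mc * (1 - mc) / 1e7)
  expect_lt(abs(p - mc), 3 * se)
  expect_error(pair_prob(0.5, 0.5, 1), "rho")
  expect_error(pair_prob(0, 0.5, 0.2), "strictly")
})

test_that("sigma blocks are exact for independence and the orthant formula", {
  mu <- c(0.5, 0.5, 0.2)
  expect_equal(sigma_block(mu, diag(3)), diag(mu * (1 - mu)))
  g <- diag(2)
  g[1, 2] <- g[2, 1] <- 0.25
  S <- sigma_block(c(0.5, 0.5), g)
  expect_equal(S[1, 2], 0.25 + asin(0.25) / (2 * pi) - 0.25)
  expect_equal(S[1, 2], 0.040215, tolerance = 1e-4)  # asin(0.25) / (2 pi)
})

test_that("sigma matches the empirical within-family residual covariance", {
  set.seed(903)
  oct <- ped_families(small_ped())[[2]]
  octped <- structure(as.data.frame(oct), class = c("pedigree", "data.frame"))
  psi <- relatedness_matrix(oct)
  X <- cbind(1, stats::runif(8), stats::rbinom(8, 1, 0.2))
  mu <- drop(stats::plogis(X %*% c(-2, 1, 1)))
  B <- 1e5
  Ymat <- matrix(0L, 8, B)
  for (b in seq_len(B)) {
    Ymat[, b] <- simulate_setting1(octped, X, NULL, c(-2, 1, 1), h2 = 0.5)
  }
  emp <- stats::cov(t(Ymat)) * (B - 1) / B
  mod <- sigma_block(mu, copula_correlation(psi, 0.5))
  # entrywise MC standard error of a covariance of Bernoullis
  se <- sqrt((outer(diag(mod), diag(mod)) + mod^2) / B)
  expect_true(all(abs(emp - mod) < 4 * se + 1e-8))
})

test_that("h2 estimation degenerates gracefully without relative pairs", {
  founders <- pedigree(rep("F", 3), c("a", "b", "c"))
  expect_warning(
    out <- estimate_h2(c(1, 0, 1), rep(0.5, 3), founders),
    "flat")
  expect_equal(out$h2_hat, 0)
  singletons <- pedigree(c("A", "B"), c("1", "1"))
  expect_error(estimate_h2(c(1, 0), rep(0.5, 2), singletons), "supply")
})

test_that("h2 pairwise-likelihood estimates track the generating value", {
  set.seed(904)
  ped <- default_pedigree_set(0, 0, 60)  # octets carry the kinship signal
  psi <- relatedness_blocks(ped)
  ests <- replicate(25, {
    X <- simulate_covariates(ped)
    Y <- simulate_setting1(ped, X, NULL, c(-2, 1, 1), h2 = 0.5,
                           psi_blocks = psi)
    fit <- fit_null_logistic(Y, X, ped$fid)
    estimate_h2(Y, fit$mu_hat, ped, psi)$h2_hat
  })
  expect_lt(abs(mean(ests) - 0.5), 0.1)
})

test_that("the score statistic matches hand arithmetic", {
  G <- rbind(c(1, 0), c(0, 1), c(2, 0), c(0, 0))
  K <- kernel_matrix(G, c(1, 1), "linear")
  res <- c(0.5, -0.5, 0.2, -0.2)
  Y <- c(1, 0, 1, 0)
  mu <- Y - res
  # Q = res' G G' res with w = 1: G'res = (0.9, -0.5)
  expect_equal(score_statistic(Y, mu, K)$Q, 0.9^2 + 0.5^2)
  expect_equal(score_statistic(Y, mu, diag(4))$Q, sum(res^2))
  expect_equal(score_statistic(Y, mu, K)$trace_K_delta,
               sum(diag(K) * mu * (1 - mu)))
  expect_equal(score_statistic(Y, Y, K)$Q, 0)
})

test_that("Omega is symmetric and converges to Sigma as families multiply", {
  set.seed(905)
  err <- vapply(c(30, 120, 480), function(I) {
    ped <- default_pedigree_set(I %/% 3, I %/% 3, I %/% 3)
    psi <- relatedness_blocks(ped)
    X <- simulate_covariates(ped)
    Y <- simulate_setting1(ped, X, NULL, c(-2, 1, 1), h2 = 0,
                           psi_blocks = psi)
    fit <- fit_null_logistic(Y, X, ped$fid)
    sig <- sigma_blocks(fit$mu_hat, ped, psi, 0)
    Om <- build_omega(fit, sig, X, ped)
    expect_equal(Om, t(Om))
    S <- block_diagonal(sig)
    c(frob = norm(Om - S, "F") / norm(S, "F"), entry = max(abs(Om - S)))
  }, numeric(2))
  # entrywise sandwich correction is O(1/I): ~4x shrink per 4x more families;
  # the aggregated Frobenius ratio shrinks like I^(-1/2)
  expect_lt(err["entry", 2], err["entry", 1] / 2.5)
  expect_lt(err["entry", 3], err["entry", 2] / 2.5)
  expect_true(all(diff(err["frob", ]) < 0))
})

test_that("model-based and empirical B estimators agree asymptotically in form", {
  set.seed(906)
  ped <- default_pedigree_set()
  psi <- relatedness_blocks(ped)
  X <- simulate_covariates(ped)
  Y <- simulate_setting1(ped, X, NULL, c(-2, 1, 1), h2 = 0.3, psi_blocks = psi)
  fit <- fit_null_logistic(Y, X, ped$fid)
  sig <- sigma_blocks(fit$mu_hat, ped, psi, 0.3)
  Om_m <- build_omega(fit, sig, X, ped, "model")
  Om_e <- build_omega(fit, sig, X, ped, "empirical")
  # same leading term; sandwich corrections are both O(1/I)
  expect_lt(norm(Om_m - Om_e, "F") / norm(Om_m, "F"), 0.05)
})

test_that("factored and full square-root eigenvalue routes coincide", {
  set.seed(907)
  ped <- default_pedigree_set(10, 10, 10)
  psi <- relatedness_blocks(ped)
  G <- simulate_genotypes(ped, region_spec(r = 4, maf = 0.3, d2 = 0.1))
  X <- simulate_covariates(ped)
  Y <- simulate_setting1(ped, X, G, c(-2, 1, 1), h2 = 0.2, psi_blocks = psi)
  fit <- fit_null_logistic(Y, X, ped$fid)
  sig <- sigma_blocks(fit$mu_hat, ped, psi, 0.2)
  Om <- build_omega(fit, sig, X, ped)
  K <- kernel_matrix(G, rep(1, 4), "linear")
  sc <- score_statistic(Y, fit$mu_hat, K)
  pv_fac <- pvalue_mixture_chisq(sc$Q, Om, K)
  Kbare <- K
  attr(Kbare, "factor") <- NULL
  pv_full <- pvalue_mixture_chisq(sc$Q, Om, Kbare)
  n <- length(pv_fac$theta)
  expect_equal(pv_fac$theta[1:n], pv_full$theta[1:n], tolerance = 1e-8)
  expect_equal(pv_fac$p_value, pv_full$p_value, tolerance = 1e-8)
  # eigenvalue sum identity: sum(theta) = tr(K Omega_+)
  expect_equal(sum(pv_full$theta), sum(diag(K %*% Om)), tolerance = 1e-6)
})

test_that("degenerate spectra raise an error", {
  Om <- diag(4) * 0.2
  K <- matrix(0, 4, 4)
  expect_error(pvalue_mixture_chisq(1, Om, K), "degenerate")
})

test_that("nrvat_test orchestrates filters, fixed h2 and reporting", {
  set.seed(908)
  ped <- default_pedigree_set()
  psi <- relatedness_blocks(ped)
  G <- simulate_genotypes(ped, region_spec(r = 10, maf = 0.05, d2 = 0.1))
  G[, 1] <- 0L  # monomorphic variant must be dropped
  X <- simulate_covariates(ped)
  Y <- simulate_setting1(ped, X, G, c(-2, 1, 1), h2 = 0.2, psi_blocks = psi)
  Y[c(3, 50)] <- NA
  G[7, 2] <- NA
  res <- nrvat_test(Y, X, G, ped, kernel = "linear", h2 = 0.2,
                    psi_blocks = psi, set_id = "demo")
  expect_s3_class(res, "nrvat_result")
  expect_equal(res$dropped_variants, "snp1")
  expect_equal(res$n_removed_subjects, 3)
  expect_equal(res$n_subjects, 597)
  expect_equal(res$h2_hat, 0.2)
  expect_gte(res$Q, 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_true(res$pvalue_method %in% c("imhof", "liu"))
  expect_error(nrvat_test(Y, X, G, ped, h2 = 2), "fixed h2")
  expect_output(print(res), "demo")
})

test_that("with unrelated singletons and h2 = 0 the test matches an independent SKAT-type oracle", {
  set.seed(909)
  n <- 400
  ped1 <- pedigree(as.character(1:n), rep("1", n))
  X <- cbind(1, stats::rnorm(n))
  G <- matrix(stats::rbinom(n * 5, 2, 0.1), n, 5,
              dimnames = list(paste(1:n, "1", sep = ":"),
                              paste0("v", 1:5)))
  Y <- stats::rbinom(n, 1, stats::plogis(-1 + X[, 2]))
  w <- rep(1, 5)
  res <- nrvat_test(Y, X, G, ped1, kernel = "linear", weights = w, h2 = 0)
  # independent small-sample oracle from the same formulas, written directly:
  # mu by IRLS via glm, Omega = V - V X (X'VX)^-1 X' V with V = diag(mu(1-mu))
  # (the I-family sandwich with one subject per family and model-based B
  # collapses to this projected form up to O(1/I); compare p-values loosely
  # and the statistic exactly)
  fit <- stats::glm(Y ~ X[, 2], family = stats::binomial())
  mu <- fit$fitted.values
  Q_oracle <- drop(crossprod(Y - mu, tcrossprod(G) %*% (Y - mu)))
  expect_equal(res$Q, Q_oracle, tolerance = 1e-8)
  V <- diag(mu * (1 - mu))
  P <- V - V %*% X %*% solve(crossprod(X, V %*% X), t(X) %*% V)
  theta_oracle <- eigen(crossprod(G, P %*% G), symmetric = TRUE,
                        only.values = TRUE)$values
  p_oracle <- imhof_tail(Q_oracle, theta_oracle)$p
  expect_equal(res$p_value, p_oracle, tolerance = 1e-6)
})
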