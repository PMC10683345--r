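test_that("covariate design is intercept + U[0,1] + Bernoulli(0.2)", {
  set.seed(601)
  big <- data.frame(fid = as.character(1:1e5), iid = "1")
  X <- simulate_covariates(big)
  expect_equal(unname(X[, 1]), rep(1, 1e5))
  expect_true(all(X[, 2] >= 0 & X[, 2] <= 1))
  ci <- stats::binom.test(sum(X[, 3]), 1e5, p = 0.2, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.2 && 0.2 <= ci[2])
})

test_that("variant effects have the variance-component law tau * w", {
  set.seed(602)
  expect_equal(draw_beta(6, 0), rep(0, 6))
  w <- c(2, 0.5, 1, 1, 1)
  b <- t(replicate(2e4, draw_beta(5, 0.3, w, causal = c(1, 2))))
  expect_equal(b[, 3:5], matrix(0, 2e4, 3))
  v <- apply(b[, 1:2], 2, stats::var)
  expect_equal(unname(v), 0.3 * w[1:2], tolerance = 0.05)
  expect_error(draw_beta(5, -1), "tau")
})

test_that("the Gaussian copula preserves marginal means for any h2", {
  set.seed(603)
  ped <- default_pedigree_set()
  X <- cbind(1, 0, 0)[rep(1, nrow(ped)), ]
  for (h2 in c(0, 0.5)) {
    y <- replicate(200, mean(simulate_setting1(ped, X, NULL, c(-2, 0, 0),
                                               h2 = h2)))
    se <- stats::sd(y) / sqrt(length(y))
    expect_lt(abs(mean(y) - stats::plogis(-2)), 4 * se + 1e-6)
  }
})

test_that("pairwise phenotype concordance equals the orthant probability", {
  set.seed(604)
  # parent-offspring pair, mu = 0.5 both, h2 = 0.5 -> latent rho = 0.25
  po <- pedigree("F", c("fa", "mo", "ch"), c("0", "0", "fa"),
                 c("0", "0", "mo"))
  X <- matrix(1, 3, 1)
  both <- replicate(4e4, {
    y <- simulate_setting1(po, X, NULL, 0, h2 = 0.5)
    y[1] * y[3]
  })
  target <- pbvnorm(0, 0, 0.25)  # 1/4 + asin(.25)/(2 pi)
  se <- sqrt(target * (1 - target) / length(both))
  expect_lt(abs(mean(both) - target), 4 * se)
})

test_that("GLMM generator has the conditional-model law", {
  set.seed(605)
  ped <- default_pedigree_set()
  X <- matrix(1, nrow(ped), 1)
  # MC oracle for the marginal prevalence integrating out b ~ N(0, h2)
  b <- stats::rnorm(1e6, 0, sqrt(0.5))
  oracle <- mean(stats::plogis(-2 + b))
  y <- replicate(150, mean(simulate_glmm(ped, X, NULL, -2, h2 = 0.5)))
  se <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - oracle), 4 * se + 1e-6)
  # h2 = 0 reduces to iid logistic sampling
  y0 <- simulate_glmm(ped, X, NULL, -2, h2 = 0)
  expect_true(all(y0 %in% 0:1))
})

test_that("t-copula thresholds shift the margin to pt(qnorm(mu), df)", {
  set.seed(606)
  ped <- default_pedigree_set()
  X <- matrix(1, nrow(ped), 1)
  mu <- stats::plogis(-2)
  target <- stats::pt(stats::qnorm(mu), df = 3)
  y <- replicate(300, mean(simulate_t_copula(ped, X, NULL, -2, h2 = 0.2)))
  se <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - target), 4 * se)
  expect_gt(abs(mean(y) - mu), 4 * se)  # mis-specification is real
  # margin-corrected flag restores mu
  yc <- replicate(300, mean(simulate_t_copula(ped, X, NULL, -2, h2 = 0.2,
                                              correct_margins = TRUE)))
  expect_lt(abs(mean(yc) - mu), 4 * stats::sd(yc) / sqrt(length(yc)))
})

test_that("chi-square copula transform has its closed forms and normal margin", {
  expect_equal(chisq_copula_transform(1, a = 0), 2 * stats::pnorm(1) - 1)
  expect_equal(chisq_copula_transform(-1, a = 1), 1e-12)  # z = -a clipped
  expect_equal(chisq_copula_transform(0, a = 0), 1e-12)   # sign(0) = 0
  set.seed(607)
  z <- stats::qnorm(chisq_copula_transform(stats::rnorm(1e5), a = 1))
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.001)
})

test_that("chi-square copula generator preserves marginal means", {
  set.seed(608)
  ped <- default_pedigree_set()
  X <- matrix(1, nrow(ped), 1)
  y <- replicate(200, mean(simulate_chisq_copula(ped, X, NULL, -2, h2 = 0.5)))
  se <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - stats::plogis(-2)), 4 * se + 1e-6)
})

test_that("missingness mechanisms hit their target rates and are listwise-ready", {
  set.seed(609)
  n <- 1e5
  ped <- data.frame(fid = as.character(1:n), iid = "1")
  X <- simulate_covariates(ped)
  Y <- stats::rbinom(n, 1, 0.2)
  expect_equal(apply_missingness(Y, X, 0), Y)
  Ym <- apply_missingness(Y, X, 0.1, "mcar")
  ci <- stats::binom.test(sum(is.na(Ym)), n, p = 0.1, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
  Ya <- apply_missingness(Y, X, 0.2, "mar")
  expect_lt(abs(mean(is.na(Ya)) - 0.2), 0.01)
  # MAR masking really depends on the covariates
  expect_gt(mean(X[is.na(Ya), 2]), mean(X[!is.na(Ya), 2]))
  expect_error(apply_missingness(Y, X, 1), "p must")
})

test_that("generators are reproducible from a seed", {
  ped <- small_ped()
  run <- function() {
    set.seed(77)
    G <- simulate_genotypes(ped, region_spec(r = 5, maf = 0.2, d2 = 0.1))
    X <- simulate_covariates(ped)
    Y <- simulate_setting1(ped, X, G, c(-2, 1, 1), h2 = 0.3)
    list(G, X, Y)
  }
  expect_identical(run(), run())
})
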