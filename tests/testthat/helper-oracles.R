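# Independent oracles used across tests. Each reimplements the quantity it
# checks from first principles (enumeration, gene dropping, Monte Carlo,
# naive double loops) so it shares no code path with the implementation.

# Monte-Carlo kinship by gene dropping: drop one locus with unique founder
# allele labels through the family `n_drops` times and estimate
# phi(a, b) = P(randomly drawn alleles are identical by descent), averaging
# the four allele-pair comparisons.
gene_drop_kinship <- function(family, n_drops = 2e4) {
  sub <- as.data.frame(family)
  n <- nrow(sub)
  ord <- nrvat:::topo_order_family(sub)
  idx <- seq_len(n)
  names(idx) <- sub$iid
  a1 <- matrix(0L, n_drops, n)  # allele labels, copy 1
  a2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (j in ord) {
    if (sub$pat[j] == "0") {
      a1[, j] <- lab + 1L
      a2[, j] <- lab + 2L
      lab <- lab + 2L
    } else {
      fa <- idx[[sub$pat[j]]]
      mo <- idx[[sub$mat[j]]]
      pick_f <- stats::runif(n_drops) < 0.5
      pick_m <- stats::runif(n_drops) < 0.5
      a1[, j] <- ifelse(pick_f, a1[, fa], a2[, fa])
      a2[, j] <- ifelse(pick_m, a1[, mo], a2[, mo])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(sub$iid, sub$iid))
  for (a in seq_len(n)) {
    for (b in a:n) {
      phi[a, b] <- phi[b, a] <- mean(
        (a1[, a] == a1[, b]) + (a1[, a] == a2[, b]) +
        (a2[, a] == a1[, b]) + (a2[, a] == a2[, b])) / 4
    }
  }
  phi
}

# Naive double-loop kernel evaluation.
naive_kernel <- function(G, w, kind, bandwidth = ncol(G), degree = 3) {
  n <- nrow(G)
  K <- matrix(0, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      inner <- sum(w * G[u, ] * G[v, ])
      K[u, v] <- switch(kind,
        linear = inner,
        quadratic = (1 + inner)^2,
        polynomial = (1 + inner)^degree,
        ibs = sum(w * (2 - abs(G[u, ] - G[v, ]))),
        gaussian = exp(-sum(w * (G[u, ] - G[v, ])^2) / bandwidth))
    }
  }
  K
}

# Monte-Carlo tail of a chi-square(1) mixture.
mc_mixture_tail <- function(q, theta, n = 1e6) {
  draws <- colSums(theta * matrix(stats::rchisq(length(theta) * n, df = 1),
                                  nrow = length(theta)))
  mean(draws > q)
}

# Monte-Carlo bivariate-normal orthant probability P(X <= h, Y <= k).
mc_orthant <- function(h, k, rho, n = 1e7) {
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  mean(x <= h & y <= k)
}

# Small fixed pedigree: one trio plus one three-generation octet.
small_ped <- function() {
  nrvat::default_pedigree_set(n_trio = 1, n_quad = 0, n_octet = 1)
}
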