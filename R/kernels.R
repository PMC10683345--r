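#' Per-variant weights from minor-allele frequencies
#'
#' Default scheme is the Beta(1, 25) density evaluated at the MAF,
#' `w_l = 25 (1 - maf_l)^24`, which up-weights rarer variants; `"flat"` gives
#' unit weights and `"custom"` passes a user vector through. Monomorphic
#' variants (MAF 0) must be filtered before weighting.
#'
#' @param maf vector of minor-allele frequencies in (0, 0.5].
#' @param scheme `"beta"`, `"flat"` or `"custom"`.
#' @param shape Beta parameters `(a1, a2)` for the `"beta"` scheme.
#' @param custom weight vector for the `"custom"` scheme.
#' @return strictly positive weight vector `w`, one entry per variant.
#' @export
maf_weights <- function(maf, scheme = c("beta", "flat", "custom"),
                        shape = c(1, 25), custom = NULL) {
  scheme <- match.arg(scheme)
  if (scheme != "custom") {
    if (any(maf <= 0)) {
      stop("MAF of 0 encountered: monomorphic variants must be filtered before weighting")
    }
    if (any(maf > 0.5)) stop("maf entries must lie in (0, 0.5]")
  }
  w <- switch(scheme,
    beta = stats::dbeta(maf, shape[1], shape[2]),
    flat = rep(1, length(maf)),
    custom = {
      if (is.null(custom)) stop("custom scheme requires a weight vector")
      custom
    })
  if (any(w <= 0)) stop("weights must be strictly positive")
  w
}

#' Genotype-similarity kernel matrices
#'
#' Builds the N x N kernel matrix K defining the quadratic score statistic:
#' \describe{
#'   \item{linear}{`K = G W G'`, entries `sum_l w_l G_ul G_vl`.}
#'   \item{quadratic}{`(1 + sum_l w_l G_ul G_vl)^2`.}
#'   \item{ibs}{`sum_l w_l (2 - |G_ul - G_vl|)`, weighted allele sharing.}
#'   \item{gaussian}{`exp(-sum_l w_l (G_ul - G_vl)^2 / bandwidth)`,
#'     bandwidth defaulting to the number of variants r.}
#'   \item{polynomial}{`(1 + sum_l w_l G_ul G_vl)^degree`, degree 3 by
#'     default.}
#' }
#' The linear kernel carries its factor `C = G W^{1/2}` in attribute
#' `"factor"` (`K = C C'`), which downstream eigenvalue computations exploit.
#'
#' @param G dosage matrix (0/1/2), individuals in rows; no missing values.
#' @param weights per-variant weights (see [maf_weights()]).
#' @param kind kernel kind.
#' @param bandwidth Gaussian kernel bandwidth (default `ncol(G)`).
#' @param degree polynomial kernel degree (default 3).
#' @return symmetric positive semidefinite N x N matrix.
#' @export
kernel_matrix <- function(G, weights = rep(1, ncol(G)),
                          kind = c("linear", "quadratic", "ibs", "gaussian",
                                   "polynomial"),
                          bandwidth = ncol(G), degree = 3) {
  kind <- match.arg(kind)
  if (anyNA(G)) stop("missing dosages: apply listwise deletion first")
  if (length(weights) != ncol(G)) stop("weights must have one entry per variant")
  Gw <- sweep(G, 2, weights, `*`)
  inner <- G %*% t(Gw)  # sum_l w_l G_ul G_vl
  K <- switch(kind,
    linear = inner,
    quadratic = (1 + inner)^2,
    polynomial = (1 + inner)^degree,
    ibs = {
      # sum_l w_l (2 - |G_ul - G_vl|); |G_u - G_v| via the three dosage levels
      d <- matrix(0, nrow(G), nrow(G))
      for (l in seq_len(ncol(G))) {
        d <- d + weights[l] * abs(outer(G[, l], G[, l], `-`))
      }
      2 * sum(weights) - d
    },
    gaussian = {
      sq <- matrix(0, nrow(G), nrow(G))
      for (l in seq_len(ncol(G))) {
        sq <- sq + weights[l] * outer(G[, l], G[, l], `-`)^2
      }
      exp(-sq / bandwidth)
    })
  K <- (K + t(K)) / 2
  if (kind == "linear") attr(K, "factor") <- sweep(G, 2, sqrt(weights), `*`)
  K
}
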