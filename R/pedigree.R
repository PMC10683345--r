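#' Pedigree objects
#'
#' A `pedigree` is an ordered collection of families, each an ordered list of
#' individuals with optional parent links. The order of appearance of families
#' and of members within a family is fixed and defines the global row order of
#' every matrix downstream (kinship, copula correlation, residual covariance,
#' kernels).
#'
#' @param fid,iid character vectors of family and individual identifiers.
#' @param pat,mid character vectors of father / mother identifiers; `"0"` or
#'   `NA` mean unknown (founder). Both must be present or both absent.
#' @param sex integer/character sex code: 1 = male, 2 = female, 0/other = unknown
#'   (PLINK dialect). Parsed but only used for covariates/reporting.
#' @return An object of class `pedigree`: a data frame with columns
#'   `fid`, `iid`, `pat`, `mat`, `sex`, `founder`, plus family bookkeeping
#'   attributes.
#' @export
pedigree <- function(fid, iid, pat = NULL, mid = NULL, sex = NULL) {
  n <- length(iid)
  fid <- as.character(fid)
  iid <- as.character(iid)
  if (length(fid) == 1) fid <- rep(fid, n)
  if (length(fid) != n) stop("fid and iid must have equal length")
  pat <- if (is.null(pat)) rep("0", n) else as.character(pat)
  mid <- if (is.null(mid)) rep("0", n) else as.character(mid)
  sex <- if (is.null(sex)) rep(0L, n) else suppressWarnings(as.integer(sex))
  sex[is.na(sex) | !(sex %in% c(1L, 2L))] <- 0L
  pat[is.na(pat)] <- "0"
  mid[is.na(mid)] <- "0"
  if (any((pat == "0") != (mid == "0"))) {
    bad <- which((pat == "0") != (mid == "0"))[1]
    stop(sprintf("individual '%s' in family '%s' has exactly one known parent; ",
                 iid[bad], fid[bad]),
         "parent links must be both present or both absent")
  }
  df <- data.frame(fid = fid, iid = iid, pat = pat, mat = mid, sex = sex,
                   founder = pat == "0", stringsAsFactors = FALSE)
  validate_pedigree(df)
  structure(df, class = c("pedigree", "data.frame"))
}

validate_pedigree <- function(df) {
  key <- paste(df$fid, df$iid)
  if (anyDuplicated(key)) {
    stop("duplicated individual id within family: ", key[duplicated(key)][1])
  }
  for (f in unique(df$fid)) {
    sub <- df[df$fid == f, , drop = FALSE]
    ids <- sub$iid
    for (j in seq_len(nrow(sub))) {
      for (p in c(sub$pat[j], sub$mat[j])) {
        if (p != "0" && !(p %in% ids)) {
          stop(sprintf("family '%s', individual '%s': parent '%s' not found in family",
                       f, sub$iid[j], p))
        }
      }
    }
    topo_order_family(sub)  # errors on cycles
  }
  invisible(df)
}

# Founder-first topological order of one family's rows; errors on cyclic ancestry.
topo_order_family <- function(sub) {
  n <- nrow(sub)
  if (n == 0) return(integer(0))
  idx <- seq_len(n)
  names(idx) <- sub$iid
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed & vapply(seq_len(n), function(j) {
      (sub$pat[j] == "0" || placed[idx[[sub$pat[j]]]]) &&
        (sub$mat[j] == "0" || placed[idx[[sub$mat[j]]]])
    }, logical(1))
    if (!any(ready)) {
      if (all(placed)) break
      stop(sprintf("family '%s': cyclic ancestry involving individual '%s'",
                   sub$fid[1], sub$iid[which(!placed)[1]]))
    }
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
    if (all(placed)) break
  }
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d families, %d individuals (%d founders, %d nonfounders)\n",
              length(unique(x$fid)), nrow(x), sum(x$founder), sum(!x$founder)))
  invisible(x)
}

#' Split a pedigree into per-family data frames (in order of appearance)
#' @param ped a [pedigree()].
#' @return named list of data frames, one per family.
#' @export
ped_families <- function(ped) {
  split(as.data.frame(ped), factor(ped$fid, levels = unique(ped$fid)))
}

#' Read a pedigree from a PED/FAM file
#'
#' Whitespace-delimited columns `FID IID PAT MAT SEX [PHENO ...]`; parent code
#' `"0"` means unknown. Trailing columns beyond the first five are ignored.
#'
#' @param path file path.
#' @param dialect `"fam"` (default) or `"ped"`; both share the leading five
#'   columns, so parsing is identical.
#' @return a [pedigree()]; zero-row files give an empty pedigree.
#' @export
read_pedigree <- function(path, dialect = c("fam", "ped")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character"),
    error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) {
    return(structure(data.frame(fid = character(0), iid = character(0),
                                pat = character(0), mat = character(0),
                                sex = integer(0), founder = logical(0),
                                stringsAsFactors = FALSE),
                     class = c("pedigree", "data.frame")))
  }
  if (ncol(tab) < 5) stop("pedigree file must have at least 5 columns (FID IID PAT MAT SEX)")
  pedigree(tab[[1]], tab[[2]], tab[[3]], tab[[4]], tab[[5]])
}

#' Write a pedigree to a FAM-style file
#'
#' Emits `FID IID PAT MAT SEX PHENO` with phenotype `-9` (missing), so that
#' `read_pedigree()` is the exact inverse on the first five columns.
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(ped$fid, ped$iid, ped$pat, ped$mat, ped$sex, -9)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Kinship matrix of one family
#'
#' Standard recursive kinship algorithm over a founder-first topological
#' order: phi(a, a) = (1 + phi(father(a), mother(a))) / 2 and
#' phi(a, b) = (phi(father(a), b) + phi(mother(a), b)) / 2 for a nonfounder `a`
#' processed after `b`. Founders of the same family are treated as unrelated and
#' non-inbred, so the diagonal is 1/2; inbred pedigrees (self-kinship > 1/2)
#' are rejected.
#'
#' @param family one family's data frame (an element of [ped_families()]), or a
#'   single-family [pedigree()].
#' @return symmetric ni x ni matrix of kinship coefficients, rows/cols named by
#'   individual id in member order.
#' @export
kinship_matrix <- function(family) {
  sub <- as.data.frame(family)
  n <- nrow(sub)
  phi <- matrix(0, n, n, dimnames = list(sub$iid, sub$iid))
  if (n == 0) return(phi)
  ord <- topo_order_family(sub)
  idx <- seq_len(n)
  names(idx) <- sub$iid
  done <- integer(0)
  for (j in ord) {
    if (sub$founder[j]) {
      phi[j, j] <- 0.5
    } else {
      fa <- idx[[sub$pat[j]]]
      mo <- idx[[sub$mat[j]]]
      phi[j, j] <- 0.5 * (1 + phi[fa, mo])
      if (phi[j, j] > 0.5 + 1e-12) {
        stop(sprintf("family '%s': individual '%s' is inbred (self-kinship %.4f > 1/2); inbred pedigrees are not supported",
                     sub$fid[1], sub$iid[j], phi[j, j]))
      }
      for (b in done) {
        if (b == j) next
        v <- 0.5 * (phi[fa, b] + phi[mo, b])
        phi[j, b] <- v
        phi[b, j] <- v
      }
    }
    done <- c(done, j)
  }
  phi
}

#' Relatedness (expected IBD-sharing) matrix of one family
#'
#' Psi = 2 * phi, twice the theoretical kinship matrix; diagonal exactly 1
#' under the no-inbreeding constraint.
#'
#' @inheritParams kinship_matrix
#' @return symmetric ni x ni matrix with unit diagonal.
#' @export
relatedness_matrix <- function(family) {
  2 * kinship_matrix(family)
}

#' Per-family relatedness blocks for a pedigree
#' @param ped a [pedigree()].
#' @return named list of Psi matrices, one per family in pedigree order.
#' @export
relatedness_blocks <- function(ped) {
  lapply(ped_families(ped), relatedness_matrix)
}

#' Copula correlation matrix Gamma = h2 * Psi + (1 - h2) * I
#'
#' The within-family correlation of the latent Gaussian vector coupling the
#' binary phenotypes: polygenic heritability `h2` scales the relatedness
#' matrix against an independent residual.
#'
#' @param psi relatedness matrix (unit diagonal).
#' @param h2 polygenic heritability in `[0, 1)`; 1 is accepted for internal
#'   boundary checks.
#' @return correlation matrix of the same dimension as `psi`.
#' @export
copula_correlation <- function(psi, h2) {
  if (!is.numeric(h2) || length(h2) != 1 || is.na(h2) || h2 < 0 || h2 > 1) {
    stop("h2 must be a single value in [0, 1]")
  }
  h2 * psi + (1 - h2) * diag(nrow(psi))
}

#' Assemble per-family blocks into a block-diagonal N x N matrix
#' @param blocks list of square matrices in family order.
#' @return block-diagonal matrix; cross-family blocks are exactly zero.
#' @export
block_diagonal <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  n <- sum(sizes)
  out <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    k <- nrow(b)
    if (k > 0) out[at + seq_len(k), at + seq_len(k)] <- b
    at <- at + k
  }
  out
}

#' The default simulation pedigree design
#'
#' 120 families: 40 parent-parent-child trios, 40 two-parent/two-child
#' quartets, and 40 three-generation octets (2 grandparents, their 2 children
#' each with a married-in spouse, and 2 grandchildren who are first cousins);
#' 600 individuals in total, 320 founders and 280 nonfounders.
#'
#' @param n_trio,n_quad,n_octet numbers of families of each template.
#' @return a [pedigree()].
#' @export
default_pedigree_set <- function(n_trio = 40, n_quad = 40, n_octet = 40) {
  rows <- list()
  add <- function(fid, iid, pat, mat, sex) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fid = fid, iid = iid, pat = pat, mat = mat, sex = sex,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_trio)) {
    f <- sprintf("T%03d", i)
    add(f, c("1", "2", "3"), c("0", "0", "1"), c("0", "0", "2"), c(1, 2, 2))
  }
  for (i in seq_len(n_quad)) {
    f <- sprintf("Q%03d", i)
    add(f, c("1", "2", "3", "4"), c("0", "0", "1", "1"),
        c("0", "0", "2", "2"), c(1, 2, 2, 2))
  }
  for (i in seq_len(n_octet)) {
    f <- sprintf("O%03d", i)
    # 1,2 grandparents; 3,5 their children; 4,6 married-in spouses; 7,8 cousins
    add(f, c("1", "2", "3", "4", "5", "6", "7", "8"),
        c("0", "0", "1", "0", "1", "0", "3", "5"),
        c("0", "0", "2", "0", "2", "0", "4", "6"),
        c(1, 2, 1, 2, 2, 1, 1, 2))
  }
  df <- do.call(rbind, rows)
  pedigree(df$fid, df$iid, df$pat, df$mat, df$sex)
}
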