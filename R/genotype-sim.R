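#' Region specification for linked-SNP simulation
#'
#' Describes one genomic region of `r` tightly linked biallelic SNPs: target
#' minor-allele frequencies and the squared correlation `d2` between the minor
#' allele indicators of adjacent SNPs. When `maf` is `NULL`, frequencies are
#' drawn independently from `Uniform(maf_range[1], maf_range[2])` at simulation
#' time (default 0.003-0.01, the rare-variant regime the test targets).
#'
#' @param r number of SNPs (default 20).
#' @param maf optional fixed vector of minor-allele frequencies in (0, 0.5].
#' @param d2 target squared correlation between adjacent SNPs, in `[0, 1)`
#'   (default 0.16).
#' @param maf_range range for random MAF draws when `maf` is `NULL`.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(r = 20, maf = NULL, d2 = 0.16,
                        maf_range = c(0.003, 0.01)) {
  if (r < 1) stop("r must be >= 1")
  if (d2 < 0 || d2 >= 1) stop("d2 must lie in [0, 1)")
  if (!is.null(maf)) {
    if (length(maf) == 1) maf <- rep(maf, r)
    if (length(maf) != r) stop("maf must have length r")
    if (any(maf <= 0 | maf > 0.5)) stop("maf entries must lie in (0, 0.5]")
  }
  structure(list(r = as.integer(r), maf = maf, d2 = d2,
                 maf_range = maf_range),
            class = "region_spec")
}

# Draw MAFs if the spec leaves them random; returns a spec with maf resolved.
resolve_region <- function(spec) {
  if (is.null(spec$maf)) {
    spec$maf <- stats::runif(spec$r, spec$maf_range[1], spec$maf_range[2])
  }
  spec
}

#' Calibrate latent correlations for a target adjacent-SNP d2
#'
#' The founder haplotype model thresholds a latent AR(1) Gaussian process at
#' `qnorm(maf_l)`. For each adjacent pair this solves, by root finding on the
#' bivariate-normal orthant probability, for the latent correlation that makes
#' the squared Pearson correlation of the two binary allele indicators equal
#' to `d2`.
#'
#' @param maf vector of minor-allele frequencies (resolved, length r).
#' @param d2 target allele-level squared correlation.
#' @return vector of length `r - 1` of latent adjacent correlations.
#' @export
calibrate_latent_ld <- function(maf, d2) {
  r <- length(maf)
  if (r < 2 || d2 == 0) return(rep(0, max(0, r - 1)))
  rb <- sqrt(d2)
  vapply(seq_len(r - 1), function(l) {
    p1 <- maf[l]
    p2 <- maf[l + 1]
    t1 <- stats::qnorm(p1)
    t2 <- stats::qnorm(p2)
    sdp <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    f <- function(rho) (pbvnorm(t1, t2, rho) - p1 * p2) / sdp - rb
    upper <- 1 - 1e-12
    if (f(upper) < 0) {
      stop(sprintf(
        "d2 = %.3g infeasible for adjacent SNP pair %d-%d (MAFs %.4g, %.4g): maximum attainable squared correlation is %.3g",
        d2, l, l + 1, p1, p2, ((min(p1, p2) - p1 * p2) / sdp)^2))
    }
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }, numeric(1))
}

#' Simulate founder haplotypes with target MAFs and adjacent-SNP LD
#'
#' Generates binary haplotypes (1 = minor allele) by thresholding a latent
#' first-order autoregressive Gaussian process at `qnorm(maf_l)`, with the
#' latent adjacent correlations calibrated so the induced allele-level squared
#' correlation matches `spec$d2` (see [calibrate_latent_ld()]).
#'
#' @param spec a [region_spec()].
#' @param n_haplotypes number of haplotypes to generate.
#' @return 0/1 matrix `n_haplotypes x r` with attributes `maf` (the resolved
#'   frequencies) and `latent_rho` (the calibrated adjacent correlations).
#' @export
simulate_founder_haplotypes <- function(spec, n_haplotypes) {
  spec <- resolve_region(spec)
  r <- spec$r
  rho <- calibrate_latent_ld(spec$maf, spec$d2)
  z <- matrix(0, n_haplotypes, r)
  z[, 1] <- stats::rnorm(n_haplotypes)
  for (l in seq_len(r - 1)) {
    z[, l + 1] <- rho[l] * z[, l] +
      sqrt(1 - rho[l]^2) * stats::rnorm(n_haplotypes)
  }
  H <- matrix(0L, n_haplotypes, r)
  thr <- stats::qnorm(spec$maf)
  for (l in seq_len(r)) H[, l] <- as.integer(z[, l] <= thr[l])
  colnames(H) <- paste0("snp", seq_len(r))
  attr(H, "maf") <- spec$maf
  attr(H, "latent_rho") <- rho
  H
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders receive consecutive haplotype pairs from `founder_haplotypes` in
#' pedigree order; each nonfounder receives one haplotype from each parent,
#' chosen uniformly among the parent's two. With `recomb = 0` (default) whole
#' haplotypes are transmitted, preserving the founder LD structure across the
#' tightly linked region; `recomb > 0` applies an independent crossover
#' probability per adjacent-SNP interval.
#'
#' @param ped a [pedigree()].
#' @param founder_haplotypes 0/1 matrix with `2 * n_founders` rows (two
#'   consecutive rows per founder, in pedigree founder order).
#' @param recomb per-interval recombination fraction in `[0, 0.5]`.
#' @return integer dosage matrix N x r (counts of the minor allele, 0/1/2) with
#'   rows named `fid:iid`. The transmitted haplotypes are kept in attribute
#'   `haplotypes`, a `2N x r` matrix with rows `2j - 1` and `2j` holding
#'   individual `j`'s paternal and maternal haplotype.
#' @export
gene_drop <- function(ped, founder_haplotypes, recomb = 0) {
  nf <- sum(ped$founder)
  if (nrow(founder_haplotypes) != 2 * nf) {
    stop(sprintf("founder_haplotypes has %d rows; pedigree needs %d (2 per founder)",
                 nrow(founder_haplotypes), 2 * nf))
  }
  r <- ncol(founder_haplotypes)
  N <- nrow(ped)
  hap <- matrix(0L, 2 * N, r)
  key <- paste(ped$fid, ped$iid, sep = ":")
  fam_rows <- split(seq_len(N), factor(ped$fid, levels = unique(ped$fid)))
  founder_global <- which(ped$founder)

  transmit <- function(pair) {
    # pair: 2 x r parental haplotypes -> one gamete
    if (recomb <= 0) {
      pair[sample.int(2L, 1L), ]
    } else {
      cur <- sample.int(2L, 1L)
      track <- cumsum(c(cur - 1L, stats::rbinom(r - 1, 1, recomb))) %% 2L
      ifelse(track == 0L, pair[1L, ], pair[2L, ])
    }
  }

  for (rows in fam_rows) {
    sub <- as.data.frame(ped[rows, , drop = FALSE])
    ord <- topo_order_family(sub)
    idx <- seq_along(rows)
    names(idx) <- sub$iid
    for (j in ord) {
      g <- rows[j]
      if (sub$founder[j]) {
        founder_ptr <- which(founder_global == g)
        hap[2 * g - 1L, ] <- founder_haplotypes[2 * founder_ptr - 1L, ]
        hap[2 * g, ] <- founder_haplotypes[2 * founder_ptr, ]
      } else {
        fa <- rows[idx[[sub$pat[j]]]]
        mo <- rows[idx[[sub$mat[j]]]]
        hap[2 * g - 1L, ] <- transmit(hap[c(2 * fa - 1L, 2 * fa), , drop = FALSE])
        hap[2 * g, ] <- transmit(hap[c(2 * mo - 1L, 2 * mo), , drop = FALSE])
      }
    }
  }
  G <- hap[seq(1, 2 * N, by = 2), , drop = FALSE] +
    hap[seq(2, 2 * N, by = 2), , drop = FALSE]
  dimnames(G) <- list(key, colnames(founder_haplotypes))
  attr(G, "haplotypes") <- hap
  G
}

#' Simulate region genotypes for a pedigree
#'
#' Convenience wrapper: founder haplotypes by [simulate_founder_haplotypes()],
#' then Mendelian [gene_drop()].
#'
#' @param ped a [pedigree()].
#' @param spec a [region_spec()].
#' @param recomb per-interval recombination fraction (default 0).
#' @return dosage matrix as in [gene_drop()], with attribute `maf` carrying the
#'   generating founder-population MAFs.
#' @export
simulate_genotypes <- function(ped, spec, recomb = 0) {
  H <- simulate_founder_haplotypes(spec, 2 * sum(ped$founder))
  G <- gene_drop(ped, H, recomb = recomb)
  attr(G, "maf") <- attr(H, "maf")
  G
}

#' Sample minor-allele frequencies from a dosage matrix
#'
#' @param G dosage matrix (0/1/2), individuals in rows.
#' @param founder optional logical vector selecting founders; when supplied,
#'   frequencies are computed from founders only (unbiased in pedigrees).
#' @return vector of allele frequencies per variant.
#' @export
sample_maf <- function(G, founder = NULL) {
  if (!is.null(founder)) G <- G[founder, , drop = FALSE]
  colMeans(G) / 2
}

#' Write / read a plain TSV dosage matrix
#'
#' Layout: columns `FID`, `IID`, then one 0/1/2 column per variant.
#'
#' @param G dosage matrix with rows named `fid:iid` (as from [gene_drop()]).
#' @param ped the matching [pedigree()] (for FID/IID columns).
#' @param path file path.
#' @export
write_dosage_tsv <- function(G, ped, path) {
  out <- data.frame(FID = ped$fid, IID = ped$iid, G, check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @return `read_dosage_tsv`: dosage matrix with rows named `fid:iid`.
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA)
  G <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- paste(tab$FID, tab$IID, sep = ":")
  G
}

#' Write genotypes as a minimal biallelic VCF
#'
#' Unphased GT records (`0/0`, `0/1`, `1/1`) with the minor allele as ALT, so
#' the dosage equals the ALT-allele count. Positions are consecutive integers
#' on a placeholder contig.
#'
#' @param G dosage matrix (0/1/2), variants in columns.
#' @param ped matching [pedigree()]; sample names are `fid:iid`.
#' @param path output path (plain text, not compressed).
#' @param chrom contig name used in the CHROM column.
#' @export
write_vcf <- function(G, ped, path, chrom = "1") {
  ids <- paste(ped$fid, ped$iid, sep = ":")
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (l in seq_len(ncol(G))) {
    writeLines(paste(c(chrom, l, colnames(G)[l], "A", "T", ".", "PASS", ".",
                       "GT", gt[G[, l] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a biallelic VCF
#'
#' Uses the `vcfR` package to parse the file and converts GT calls to ALT
#' allele counts. Variants with non-biallelic ALT fields are rejected.
#'
#' @param path VCF path.
#' @return dosage matrix, individuals in rows (sample names), variants in
#'   columns (ID column, or `chrom_pos` when missing).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) stop("multiallelic variants are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
  cnt <- nchar(gsub("[^1]", "", gt))
  dim(cnt) <- dim(gt)
  cnt[is.na(gt) | grepl("\\.", gt)] <- NA_integer_
  ids <- vcfR::getID(v)
  if (all(is.na(ids))) {
    ids <- paste(vcfR::getCHROM(v), vcfR::getPOS(v), sep = "_")
  }
  G <- t(cnt)  # individuals in rows
  dimnames(G) <- list(colnames(gt), ids)
  G
}
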