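# Tabular I/O for the command-line workflow: phenotype/covariate tables,
# SetID variant-set definitions, and results.

#' Read a phenotype/covariate table
#'
#' Tab-separated with header `FID IID Y X1 [X2 ...]`; `NA` marks missing.
#'
#' @param path file path.
#' @return list with `fid`, `iid`, `Y` (numeric vector) and `X` (matrix with a
#'   leading intercept column).
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  need <- c("FID", "IID", "Y")
  if (!all(need %in% names(tab))) {
    stop("phenotype table must have columns FID, IID, Y")
  }
  covars <- setdiff(names(tab), need)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(tab[, covars, drop = FALSE]))
  list(fid = as.character(tab$FID), iid = as.character(tab$IID),
       Y = as.numeric(tab$Y), X = X)
}

#' Write a phenotype/covariate table
#'
#' @param Y phenotype vector.
#' @param X covariate matrix (intercept column dropped on output).
#' @param ped matching [pedigree()].
#' @param path file path.
#' @export
write_phenotype_table <- function(Y, X, ped, path) {
  out <- data.frame(FID = ped$fid, IID = ped$iid, Y = Y,
                    X[, -1, drop = FALSE], check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a SetID variant-set definition file
#'
#' Two whitespace-delimited columns: set name, variant id (SKAT SetID layout).
#'
#' @param path file path.
#' @return named list mapping set name to character vector of variant ids.
#' @export
read_setid <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("SetID file needs two columns: set id, variant id")
  split(tab[[2]], factor(tab[[1]], levels = unique(tab[[1]])))
}

#' Flatten test results to a data frame / TSV
#'
#' @param results list of `nrvat_result` objects.
#' @param path optional output path; when given, written as TSV.
#' @return data frame with one row per variant set.
#' @export
results_table <- function(results, path = NULL) {
  df <- do.call(rbind, lapply(results, function(x) {
    data.frame(set_id = x$set_id, n_subjects = x$n_subjects,
               n_variants = x$n_variants, kernel = x$kernel,
               h2_hat = x$h2_hat, Q = x$Q, p_value = x$p_value,
               pvalue_method = x$pvalue_method,
               n_dropped_variants = length(x$dropped_variants),
               n_removed_subjects = x$n_removed_subjects)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  }
  df
}
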