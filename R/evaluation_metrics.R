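#' Root mean square error
#'
#' \deqn{RMSE = \sqrt{\sum_i (y_i - \hat y_i)^2 / n}}
#'
#' @param actual,predicted numeric vectors of equal length >= 1.
#' @return nonnegative scalar.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) == 0L)
    stop("rmse: vectors must have equal, nonzero length")
  sqrt(mean((actual - predicted)^2))
}

#' Coefficient R-squared
#'
#' Default is the squared Pearson correlation between actual and predicted
#' values (the convention when R-squared is reported as a "correlation
#' coefficient"). The coefficient-of-determination variant
#' \eqn{1 - SS_{res}/SS_{tot}} is selectable; it can be negative and
#' penalizes biased predictions, so the two differ for anti-correlated or
#' offset predictions.
#'
#' @param actual,predicted numeric vectors, length >= 2; `actual` must not
#'   be constant.
#' @param method `"pearson"` (default) or `"determination"`.
#' @param verbose if `TRUE`, return both variants as a named list.
#' @return scalar (or named list when `verbose`).
#' @export
r_squared <- function(actual, predicted, method = c("pearson", "determination"),
                      verbose = FALSE) {
  method <- match.arg(method)
  if (length(actual) != length(predicted) || length(actual) < 2L)
    stop("r_squared: vectors must have equal length >= 2")
  if (stats::sd(actual) == 0) stop("r_squared undefined for constant actual values")
  pear <- if (stats::sd(predicted) == 0) 0 else stats::cor(actual, predicted)^2
  detn <- 1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)
  if (verbose) return(list(pearson = pear, determination = detn))
  if (method == "pearson") pear else detn
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from ranks; tied scores contribute
#' 1/2, so all-equal scores give 0.5. Invariant under any strictly
#' monotone transform of the scores.
#'
#' @param labels binary vector (0/1 or logical); both classes must be
#'   present.
#' @param scores numeric scores, higher = more positive.
#' @return scalar in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores)) stop("auc: length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Combined metric report
#'
#' @param actual,predicted numeric vectors.
#' @param labels optional binary labels for AUC of `predicted` as a score.
#' @return a `metric_report` list with `r2`, `rmse`, `auc` (or `NA`), `n`.
#' @export
metric_report <- function(actual, predicted, labels = NULL) {
  structure(list(
    r2 = r_squared(actual, predicted),
    rmse = rmse(actual, predicted),
    auc = if (is.null(labels)) NA_real_ else auc(labels, predicted),
    n = length(actual)
  ), class = "metric_report")
}

#' PCA chemical-space check
#'
#' Standardizes the named descriptor columns (PCA on the correlation
#' matrix, since the descriptors carry incommensurate units) and returns
#' the first three principal-component scores per compound tagged by fold,
#' together with the variance fraction of every component. Used to verify
#' that stratified folds cover the same region of chemical space.
#'
#' @param descriptor_table a `descriptor_table` (see
#'   [compute_descriptors()]) or plain data.frame of numeric columns.
#' @param descriptor_names character vector of column names to use
#'   (typically the 11 representative descriptors, see
#'   [chemical_space_descriptors()]).
#' @param fold_assignment integer/factor fold per compound, or `NULL`.
#' @return list with `scores` (data.frame: compound_id, fold, PC1..PC3),
#'   `variance_fraction` (all components, non-increasing), and `loadings`.
#' @export
pca_space <- function(descriptor_table, descriptor_names, fold_assignment = NULL) {
  x <- descriptor_data(descriptor_table)
  missing <- setdiff(descriptor_names, colnames(x))
  if (length(missing))
    stop("pca_space: descriptor column(s) absent: ", paste(missing, collapse = ", "))
  m <- as.matrix(x[, descriptor_names, drop = FALSE])
  const <- apply(m, 2L, stats::sd) == 0
  if (any(const))
    stop("pca_space: constant descriptor column(s): ",
         paste(descriptor_names[const], collapse = ", "))
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  k <- min(3L, ncol(p$x))
  scores <- data.frame(compound_id = descriptor_ids(descriptor_table, nrow(m)),
                       fold = if (is.null(fold_assignment)) NA else fold_assignment,
                       p$x[, seq_len(k), drop = FALSE])
  list(scores = scores, variance_fraction = vf, loadings = p$rotation)
}

#' The 11 representative chemical-space descriptors
#'
#' Size, lipophilicity, polarity, hydrogen bonding, aromaticity,
#' flexibility and charge-state proxies: the descriptor set used for the
#' PCA chemical-space check.
#' @return character vector of 11 descriptor names.
#' @export
chemical_space_descriptors <- function() {
  c("mw", "slogp", "tpsa", "hba", "hbd", "n_aromatic_atoms",
    "n_aromatic_bonds", "n_rotatable_bonds", "n_basic_n", "n_acidic_o",
    "logd_proxy")
}

# Accept either the package's descriptor_table or a plain data.frame.
descriptor_data <- function(x) {
  if (inherits(x, "descriptor_table")) x$data else as.data.frame(x)
}
descriptor_ids <- function(x, n) {
  if (inherits(x, "descriptor_table")) x$compound_ids
  else rownames(descriptor_data(x)) %||% as.character(seq_len(n))
}
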