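#' Stratified allocation of ids into parts
#'
#' Deterministically assigns ids to `length(fractions)` parts so that (a)
#' part sizes follow the fractions by the largest-remainder rule and (b)
#' within every stratum the class proportion of each part is within one
#' compound of the global proportion. Strata smaller than the number of
#' parts cannot be stratified and are pooled and allocated unstratified
#' (logged).
#'
#' @param ids character vector of ids.
#' @param labels stratification labels aligned with `ids`.
#' @param fractions positive numeric part fractions (normalized to sum 1).
#' @param seed integer seed; the allocation is a pure function of
#'   (id order, labels, fractions, seed).
#' @return integer vector of part indices (1-based), named by id.
#' @export
stratified_allocate <- function(ids, labels, fractions, seed) {
  stopifnot(length(ids) == length(labels), all(fractions > 0))
  n <- length(ids)
  k <- length(fractions)
  fr <- fractions / sum(fractions)

  # part totals by largest remainder
  ideal <- n * fr
  tot <- floor(ideal)
  rem <- ideal - tot
  extra <- order(-rem, seq_len(k))[seq_len(n - sum(tot))]
  tot[extra] <- tot[extra] + 1L

  labs <- as.character(labels)
  sizes <- table(labs)
  small <- names(sizes)[sizes < k]
  if (length(small)) {
    sq_log("split", "pooling %d stratum(e) smaller than %d parts (unstratified fallback)",
           length(small), k)
    labs[labs %in% small] <- ".pooled_small"
  }
  strata <- unique(labs)

  # per-stratum quotas: floor of proportional share, then fill remaining
  # slots by descending fractional remainder under row/column feasibility
  q <- outer(vapply(strata, function(s) sum(labs == s), 0L), tot) / n
  fl <- floor(q)
  row_def <- vapply(strata, function(s) sum(labs == s), 0L) - rowSums(fl)
  col_def <- tot - colSums(fl)
  frac <- q - fl
  cells <- order(-as.vector(frac), seq_along(frac))
  cap <- ceiling(q)
  # controlled rounding: distribute the remaining slots so that every
  # cell stays within [floor(q), ceiling(q)] while meeting the exact row
  # (stratum) and column (part) totals. A remainder-greedy pass places
  # most units; the rest is a feasibility flow (such a rounding always
  # exists - the constraint matrix is totally unimodular).
  for (cell in cells) {
    s <- ((cell - 1L) %% length(strata)) + 1L
    p <- ((cell - 1L) %/% length(strata)) + 1L
    if (row_def[s] > 0L && col_def[p] > 0L && fl[s, p] < cap[s, p]) {
      fl[s, p] <- fl[s, p] + 1L
      row_def[s] <- row_def[s] - 1L
      col_def[p] <- col_def[p] - 1L
    }
  }
  if (sum(row_def) > 0L)
    fl <- round_by_flow(fl, floor(q), cap, row_def, col_def)

  assignment <- integer(n)
  sq_with_seed(seed, {
    for (si in seq_along(strata)) {
      idx <- which(labs == strata[si])
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep.int(seq_len(k), fl[si, ])
    }
  })
  stats::setNames(assignment, ids)
}

# Saturate remaining row/column deficits of the rounding matrix by unit
# augmenting paths (BFS) through cells with spare capacity, allowing
# reallocation of already-placed units. Deterministic: fixed scan order.
round_by_flow <- function(fl, lo, cap, row_def, col_def) {
  ns <- nrow(fl); np <- ncol(fl)
  while (sum(row_def) > 0L) {
    s0 <- which(row_def > 0L)[1L]
    # BFS over alternating stratum/part nodes; parent bookkeeping
    seen_p <- rep(FALSE, np); seen_s <- rep(FALSE, ns)
    seen_s[s0] <- TRUE
    par_p <- rep(NA_integer_, np)  # part reached from stratum
    par_s <- rep(NA_integer_, ns)  # stratum reached from part
    queue_s <- s0; queue_p <- integer()
    goal <- NA_integer_
    while (is.na(goal) && (length(queue_s) || length(queue_p))) {
      if (length(queue_s)) {
        s <- queue_s[1L]; queue_s <- queue_s[-1L]
        for (p in which(!seen_p & fl[s, ] < cap[s, ])) {
          seen_p[p] <- TRUE; par_p[p] <- s; queue_p <- c(queue_p, p)
          if (col_def[p] > 0L) { goal <- p; break }
        }
      } else {
        p <- queue_p[1L]; queue_p <- queue_p[-1L]
        for (s in which(!seen_s & fl[, p] > lo[, p])) {
          seen_s[s] <- TRUE; par_s[s] <- p; queue_s <- c(queue_s, s)
        }
      }
    }
    if (is.na(goal)) stop("internal error: infeasible stratified allocation")
    # walk back the alternating path, shifting one unit along it
    p <- goal
    repeat {
      s <- par_p[p]
      fl[s, p] <- fl[s, p] + 1L
      if (s == s0 && row_def[s0] > 0L) break
      p2 <- par_s[s]
      fl[s, p2] <- fl[s, p2] - 1L
      p <- p2
      if (is.na(par_p[p])) stop("internal error: broken augmenting path")
    }
    row_def[s0] <- row_def[s0] - 1L
    col_def[goal] <- col_def[goal] - 1L
  }
  fl
}

# Deterministic quintile bins of a numeric vector (rank-based, ties by
# first occurrence), used to stratify the regression splits on the
# endpoint distribution.
#' Quintile bins of the log endpoint
#' @param x numeric vector.
#' @param k number of bins (default 5).
#' @return integer bins 1..k aligned with `x`.
#' @export
endpoint_quantile_bins <- function(x, k = 5L) {
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * k / length(x)) + 1L)
}

#' Split one pattern's training ids for the image classifier
#'
#' Stratified 3:1 partition of the pattern's training ids into classifier
#' training and validation sets.
#'
#' @param pattern a pattern entry of a [make_split_plan()] plan (or any
#'   list with `train_ids` and `class_labels`).
#' @param seed integer seed.
#' @return list with `train_ids` and `val_ids`.
#' @export
deepsnap_partition <- function(pattern, seed) {
  a <- stratified_allocate(pattern$train_ids,
                           pattern$class_labels[pattern$train_ids],
                           c(3, 1), seed)
  list(train_ids = names(a)[a == 1L], val_ids = names(a)[a == 2L])
}

#' Split one pattern's training ids for regression
#'
#' Reserves a stratified 20% hold-out from the pattern's training ids and
#' assigns the remainder to five stratified cross-validation folds.
#'
#' @param pattern a pattern entry with `train_ids` and `regression_strata`.
#' @param seed integer seed.
#' @return list with `fit_ids`, `holdout_ids`, and `cv_assignment`
#'   (integer 1..5 named by id over `fit_ids`).
#' @export
regression_partition <- function(pattern, seed) {
  strat <- pattern$regression_strata[pattern$train_ids]
  a <- stratified_allocate(pattern$train_ids, strat, c(0.8, 0.2), seed)
  fit_ids <- names(a)[a == 1L]
  holdout_ids <- names(a)[a == 2L]
  cv <- stratified_allocate(fit_ids, pattern$regression_strata[fit_ids],
                            rep(1, 5L), derive_seed(seed, 1L))
  list(fit_ids = fit_ids, holdout_ids = holdout_ids, cv_assignment = cv)
}

#' Build the nested five-fold / five-pattern split plan
#'
#' Partitions the ids into five stratified folds of near-equal size; each
#' of the five patterns holds out one fold as the external test set and
#' takes the union of the other four as training. Within each pattern the
#' training ids are further split 3:1 into classifier training/validation
#' (stratified on the class label) and, independently, into an 80/20
#' regression fit/hold-out split plus a stratified five-fold CV assignment
#' (stratified on `regression_strata`, typically endpoint quintiles).
#'
#' @param ids character ids (length >= 10).
#' @param strat_labels class labels aligned with `ids` (used for fold and
#'   classifier stratification).
#' @param seed master integer seed; per-pattern sub-seeds are derived by
#'   fixed offsets.
#' @param regression_strata optional stratification variable for the
#'   regression splits aligned with `ids`; defaults to `strat_labels`.
#' @return a `split_plan` list: `ids`, `folds` (1..5 named by id),
#'   `patterns` (5 entries), `seed`.
#' @export
make_split_plan <- function(ids, strat_labels, seed, regression_strata = NULL) {
  stopifnot(length(ids) >= 10L, length(strat_labels) == length(ids))
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (is.null(regression_strata)) regression_strata <- strat_labels
  class_labels <- stats::setNames(strat_labels, ids)
  reg_strata <- stats::setNames(regression_strata, ids)
  folds <- stratified_allocate(ids, strat_labels, rep(1, 5L), derive_seed(seed, 0L))
  patterns <- lapply(1:5, function(p) {
    test_ids <- names(folds)[folds == p]
    train_ids <- names(folds)[folds != p]
    pat <- list(index = p, test_fold = p, test_ids = test_ids,
                train_ids = train_ids, class_labels = class_labels,
                regression_strata = reg_strata)
    ds <- deepsnap_partition(pat, derive_seed(seed, 10L + p))
    rg <- regression_partition(pat, derive_seed(seed, 20L + p))
    c(pat, list(deepsnap_train_ids = ds$train_ids, deepsnap_val_ids = ds$val_ids,
                regression_fit_ids = rg$fit_ids,
                regression_holdout_ids = rg$holdout_ids,
                cv_assignment = rg$cv_assignment))
  })
  structure(list(ids = ids, folds = folds, patterns = patterns, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  fs <- table(x$folds)
  cat(sprintf("<split_plan> %d ids; folds: %s; 5 patterns (train %d / test %d)\n",
              length(x$ids), paste(fs, collapse = "/"),
              length(x$patterns[[1L]]$train_ids),
              length(x$patterns[[1L]]$test_ids)))
  invisible(x)
}

#' Serialize / restore a split plan as delimited text
#'
#' One row per compound: its fold, plus per pattern the classifier role
#' (`train`/`val`/`test`) and regression role (`cv1`..`cv5`/`holdout`/
#' `test`), so downstream stages are restartable from a plain-text file.
#'
#' @param plan a `split_plan`.
#' @param path file path.
#' @export
write_split_plan <- function(plan, path) {
  tab <- data.frame(compound_id = plan$ids,
                    fold = unname(plan$folds[plan$ids]),
                    stringsAsFactors = FALSE)
  for (p in plan$patterns) {
    cls <- ifelse(tab$compound_id %in% p$test_ids, "test",
           ifelse(tab$compound_id %in% p$deepsnap_train_ids, "train", "val"))
    reg <- ifelse(tab$compound_id %in% p$test_ids, "test",
           ifelse(tab$compound_id %in% p$regression_holdout_ids, "holdout",
                  paste0("cv", p$cv_assignment[tab$compound_id])))
    tab[[sprintf("classifier_p%d", p$index)]] <- cls
    tab[[sprintf("regression_p%d", p$index)]] <- reg
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#seed: %d", plan$seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seed <- as.integer(sub("#seed: ", "", lines[startsWith(lines, "#seed")], fixed = TRUE))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  folds <- stats::setNames(tab$fold, tab$compound_id)
  patterns <- lapply(1:5, function(p) {
    cls <- tab[[sprintf("classifier_p%d", p)]]
    reg <- tab[[sprintf("regression_p%d", p)]]
    cv_ids <- tab$compound_id[startsWith(reg, "cv")]
    list(index = p, test_fold = p,
         test_ids = tab$compound_id[cls == "test"],
         train_ids = tab$compound_id[cls != "test"],
         deepsnap_train_ids = tab$compound_id[cls == "train"],
         deepsnap_val_ids = tab$compound_id[cls == "val"],
         regression_fit_ids = cv_ids,
         regression_holdout_ids = tab$compound_id[reg == "holdout"],
         cv_assignment = stats::setNames(
           as.integer(sub("cv", "", reg[startsWith(reg, "cv")])), cv_ids))
  })
  structure(list(ids = tab$compound_id, folds = folds, patterns = patterns,
                 seed = seed), class = "split_plan")
}
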