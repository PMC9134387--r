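#' Feature matrix for regression
#'
#' Binds compound ids, a numeric feature matrix and the log-endpoint
#' target into one aligned container.
#'
#' @param x numeric matrix with rownames = compound ids.
#' @param target named numeric log-endpoint vector covering the rows.
#' @return a `feature_matrix` list.
#' @export
feature_matrix <- function(x, target) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (!all(rownames(x) %in% names(target)))
    stop("target missing for some compounds")
  structure(list(compound_ids = rownames(x), x = x,
                 target = target[rownames(x)]),
            class = "feature_matrix")
}

#' Append the classifier probability as an extra feature
#'
#' Builds the combination feature set: the descriptor columns untouched
#' plus one extra column `deepsnap_probability` holding each compound's
#' median snapshot probability.
#'
#' @param matrix a `feature_matrix` of descriptors.
#' @param probabilities a `probability_table` (see
#'   [predict_probabilities()]) or named numeric vector.
#' @return a `feature_matrix` with exactly one additional column.
#' @export
combine_features <- function(matrix, probabilities) {
  stopifnot(inherits(matrix, "feature_matrix"))
  p <- if (inherits(probabilities, "probability_table"))
    stats::setNames(probabilities$median_probability, probabilities$compound_id)
  else probabilities
  miss <- setdiff(matrix$compound_ids, names(p))
  if (length(miss))
    stop("missing probability for compound(s): ", paste(miss, collapse = ", "))
  x <- cbind(matrix$x, deepsnap_probability = unname(p[matrix$compound_ids]))
  feature_matrix(x, matrix$target)
}

# ---- preprocessing shared by all entrants -----------------------------------
# Train-row median imputation + z-scoring, with statistics frozen on the
# training rows (constant columns get unit scale).
fit_preprocessor <- function(x) {
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- med[j]
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(median = med, mean = mu, sd = sdv)
}

apply_preprocessor <- function(prep, x) {
  for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- prep$median[j]
  sweep(sweep(x, 2L, prep$mean), 2L, prep$sd, "/")
}

# ---- algorithm registry -----------------------------------------------------

#' Default regression algorithm registry
#'
#' A fixed roster of entrants for the modeling competition, mirroring the
#' algorithm families commonly fielded by automated platforms: elastic
#' net, random forest, gradient-boosted trees, support-vector regression
#' and a shallow neural network. Hyperparameters are small fixed choices,
#' not tuned per dataset; each entrant standardizes and median-imputes
#' its inputs with training-row statistics. Registry order is the
#' tie-break order of the competition.
#'
#' @param names optional subset of entrant names to include, in registry
#'   order.
#' @return named list of entrants, each with `fit(x, y, seed)` and
#'   `predict(model, x)`.
#' @export
default_algorithm_registry <- function(names = NULL) {
  reg <- list(
    elastic_net = list(
      fit = function(x, y, seed) {
        prep <- fit_preprocessor(x)
        xs <- apply_preprocessor(prep, x)
        foldid <- sq_with_seed(seed, sample(rep_len(1:5, nrow(xs))))
        # small CV folds trigger a benign grouped=FALSE notice
        cv <- suppressWarnings(glmnet::cv.glmnet(xs, y, alpha = 0.5,
                                                 foldid = foldid,
                                                 standardize = FALSE))
        list(prep = prep, fit = cv, lambda = cv$lambda.min)
      },
      predict = function(m, x)
        as.vector(stats::predict(m$fit, apply_preprocessor(m$prep, x), s = m$lambda))
    ),
    random_forest = list(
      fit = function(x, y, seed) {
        prep <- fit_preprocessor(x)
        xs <- apply_preprocessor(prep, x)
        fit <- ranger::ranger(y = y, x = as.data.frame(xs), num.trees = 300L,
                              seed = seed, num.threads = 1L)
        list(prep = prep, fit = fit)
      },
      predict = function(m, x)
        stats::predict(m$fit, data = as.data.frame(apply_preprocessor(m$prep, x)),
                       num.threads = 1L)$predictions
    ),
    gradient_boosting = list(
      fit = function(x, y, seed) {
        prep <- fit_preprocessor(x)
        xs <- apply_preprocessor(prep, x)
        fit <- sq_with_seed(seed, xgboost::xgb.train(
          params = list(eta = 0.1, max_depth = 4L, subsample = 0.8,
                        nthread = 1L, objective = "reg:squarederror"),
          data = xgboost::xgb.DMatrix(xs, label = y, nthread = 1L),
          nrounds = 150L, verbose = 0))
        list(prep = prep, fit = fit)
      },
      predict = function(m, x)
        as.vector(stats::predict(
          m$fit, xgboost::xgb.DMatrix(apply_preprocessor(m$prep, x), nthread = 1L)))
    ),
    svr = list(
      fit = function(x, y, seed) {
        prep <- fit_preprocessor(x)
        xs <- apply_preprocessor(prep, x)
        fit <- e1071::svm(xs, y, kernel = "radial", cost = 1, scale = FALSE)
        list(prep = prep, fit = fit)
      },
      predict = function(m, x)
        as.vector(stats::predict(m$fit, apply_preprocessor(m$prep, x)))
    ),
    neural_net = list(
      fit = function(x, y, seed) {
        prep <- fit_preprocessor(x)
        xs <- apply_preprocessor(prep, x)
        fit <- sq_with_seed(seed, nnet::nnet(
          xs, y, size = 8L, decay = 0.1, linout = TRUE, maxit = 300L,
          trace = FALSE, MaxNWts = 100000L))
        list(prep = prep, fit = fit)
      },
      predict = function(m, x)
        as.vector(stats::predict(m$fit, apply_preprocessor(m$prep, x)))
    )
  )
  if (!is.null(names)) {
    unknown <- setdiff(names, base::names(reg))
    if (length(unknown)) stop("unknown entrant(s): ", paste(unknown, collapse = ", "))
    reg <- reg[base::names(reg) %in% names]
  }
  reg
}

#' Run the regression algorithm competition for one pattern
#'
#' Scores every registry entrant by stratified five-fold cross-validated
#' RMSE on the pattern's fit rows; the entrant with the lowest CV RMSE
#' wins (ties resolve to the earlier registry position). The winner is
#' then fit on the fit rows to score the 20% hold-out, and refit on the
#' full training rows (fit + hold-out) to score the external test fold.
#' Entrants that error are excluded with a log entry; the competition
#' fails only if every entrant fails. Fully deterministic given `seed`.
#'
#' @param matrix a `feature_matrix` covering all ids in the partition.
#' @param partition list with `fit_ids`, `holdout_ids`, `cv_assignment`,
#'   `train_ids`, `test_ids` (a [make_split_plan()] pattern works).
#' @param registry an algorithm registry (default
#'   [default_algorithm_registry()]).
#' @param seed integer seed.
#' @return a `competition_result`: `cv_table` (per-entrant CV RMSE),
#'   `chosen`, `model_step1`, `model_final`, `metrics` (internal /
#'   holdout / test R2 and RMSE), and out-of-fold/holdout/test
#'   predictions.
#' @export
run_competition <- function(matrix, partition,
                            registry = default_algorithm_registry(),
                            seed = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"), length(registry) >= 1L)
  fit_ids <- partition$regression_fit_ids %||% partition$fit_ids
  holdout_ids <- partition$regression_holdout_ids %||% partition$holdout_ids
  cv <- partition$cv_assignment
  train_ids <- partition$train_ids %||% c(fit_ids, holdout_ids)
  test_ids <- partition$test_ids %||% character()
  idx <- function(ids) match(ids, matrix$compound_ids)

  xf <- matrix$x[idx(fit_ids), , drop = FALSE]
  yf <- matrix$target[fit_ids]
  cvf <- cv[fit_ids]

  oof_by_algo <- list()
  cv_rmse <- rep(NA_real_, length(registry))
  names(cv_rmse) <- names(registry)
  for (a in seq_along(registry)) {
    ent <- registry[[a]]
    oof <- rep(NA_real_, length(yf))
    ok <- TRUE
    for (k in sort(unique(cvf))) {
      tr <- cvf != k
      m <- tryCatch(ent$fit(xf[tr, , drop = FALSE], yf[tr],
                            derive_seed(seed, 100L * a + k)),
                    error = function(e) e)
      if (inherits(m, "error")) { ok <- FALSE; break }
      pr <- tryCatch(ent$predict(m, xf[!tr, , drop = FALSE]),
                     error = function(e) e)
      if (inherits(pr, "error")) { ok <- FALSE; break }
      oof[!tr] <- pr
    }
    if (!ok) {
      sq_log("competition", "entrant %s failed; excluded", names(registry)[a])
      next
    }
    cv_rmse[a] <- rmse(yf, oof)
    oof_by_algo[[names(registry)[a]]] <- oof
  }
  if (all(is.na(cv_rmse))) stop("all competition entrants failed")
  chosen_idx <- which(cv_rmse == min(cv_rmse, na.rm = TRUE))[1L]
  chosen <- names(registry)[chosen_idx]
  oof <- oof_by_algo[[chosen]]

  ent <- registry[[chosen_idx]]
  model_step1 <- ent$fit(xf, yf, derive_seed(seed, 1000L + chosen_idx))
  ph <- ent$predict(model_step1, matrix$x[idx(holdout_ids), , drop = FALSE])
  xt <- matrix$x[idx(train_ids), , drop = FALSE]
  model_final <- ent$fit(xt, matrix$target[train_ids],
                         derive_seed(seed, 2000L + chosen_idx))
  pt <- if (length(test_ids))
    ent$predict(model_final, matrix$x[idx(test_ids), , drop = FALSE]) else numeric()

  metrics <- rbind(
    data.frame(set = "internal", r2 = r_squared(yf, oof), rmse = rmse(yf, oof),
               n = length(yf)),
    data.frame(set = "holdout", r2 = r_squared(matrix$target[holdout_ids], ph),
               rmse = rmse(matrix$target[holdout_ids], ph), n = length(ph)),
    if (length(test_ids))
      data.frame(set = "test", r2 = r_squared(matrix$target[test_ids], pt),
                 rmse = rmse(matrix$target[test_ids], pt), n = length(pt)))
  sq_log("competition", "chosen %s (cv_rmse=%.4f)", chosen, cv_rmse[chosen_idx])
  structure(list(
    cv_table = data.frame(algorithm = names(registry), cv_rmse = unname(cv_rmse)),
    chosen = chosen, entrant = ent,
    model_step1 = model_step1, model_final = model_final,
    metrics = metrics,
    predictions = list(
      oof = stats::setNames(oof, fit_ids),
      holdout = stats::setNames(ph, holdout_ids),
      test = stats::setNames(pt, test_ids))
  ), class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("<competition_result> chosen=%s\n", x$chosen))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Average the predictions of several fitted models
#'
#' The "average" ensembling method: per-row arithmetic mean of member
#' predictions.
#'
#' @param models list (>= 2) of fitted models, each a list with an
#'   `entrant` (having `$predict`) and `model` element, or a
#'   `competition_result` (its final model is used).
#' @param x numeric feature matrix to predict.
#' @return numeric vector of ensembled predictions.
#' @export
ensemble_average <- function(models, x) {
  if (length(models) < 2L) stop("ensemble requires at least two models")
  preds <- lapply(models, function(m) {
    p <- if (inherits(m, "competition_result"))
      m$entrant$predict(m$model_final, x)
    else m$entrant$predict(m$model, x)
    if (length(p) != nrow(x)) stop("prediction length mismatch in ensemble")
    p
  })
  rowMeans(do.call(cbind, preds))
}

#' Permutation feature importance for one pattern
#'
#' Raw importance of a feature is the mean increase of validation RMSE
#' over `n_repeats` independent shuffles of that column (negative values
#' clamp to zero); normalized importance divides by the pattern's maximal
#' raw importance so the top feature scores exactly 1.
#'
#' @param model a fitted model (`list(prep, fit)` from a registry entrant).
#' @param entrant the registry entrant that produced `model`.
#' @param x validation feature matrix.
#' @param y validation targets.
#' @param n_repeats shuffles per feature (>= 1).
#' @param seed integer seed.
#' @param normalize divide by the maximal raw importance (default TRUE).
#' @return an `importance_table` data.frame (`feature`, `raw`,
#'   `normalized`), in column order.
#' @export
permutation_importance <- function(model, entrant, x, y, n_repeats = 10L,
                                   seed = 1L, normalize = TRUE) {
  stopifnot(n_repeats >= 1L)
  base <- rmse(y, entrant$predict(model, x))
  raw <- numeric(ncol(x))
  sq_with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      inc <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        inc[r] <- rmse(y, entrant$predict(model, xp)) - base
      }
      raw[j] <- mean(inc)
    }
  })
  raw <- pmax(raw, 0)
  if (normalize && max(raw) <= 0)
    stop("all permutation importances are zero; degenerate model")
  structure(data.frame(feature = colnames(x), raw = raw,
                       normalized = if (normalize) raw / max(raw) else raw,
                       stringsAsFactors = FALSE),
            class = c("importance_table", "data.frame"))
}

#' Average effect of features over the five patterns
#'
#' Arithmetic mean of the per-pattern normalized importances over the
#' shared feature universe; a feature absent from a pattern contributes 0
#' for that pattern. Result sorted by descending average effect (ties by
#' feature name).
#'
#' @param per_pattern_tables list of `importance_table`s (typically 5).
#' @return data.frame (`feature`, `average_effect`), descending.
#' @export
average_effect <- function(per_pattern_tables) {
  feats <- sort(unique(unlist(lapply(per_pattern_tables, `[[`, "feature"))))
  m <- vapply(per_pattern_tables, function(tab) {
    v <- stats::setNames(tab$normalized, tab$feature)[feats]
    v[is.na(v)] <- 0
    v
  }, numeric(length(feats)))
  avg <- rowMeans(m)
  out <- data.frame(feature = feats, average_effect = unname(avg),
                    stringsAsFactors = FALSE)
  out[order(-out$average_effect, out$feature), , drop = FALSE]
}
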