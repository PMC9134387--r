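# Deterministic toy entrants used to probe the selection contract without
# fitting real learners.
toy_registry <- function() {
  mean_entrant <- list(
    fit = function(x, y, seed) list(mu = mean(y)),
    predict = function(m, x) rep(m$mu, nrow(x)))
  list(mean_a = mean_entrant, mean_b = mean_entrant,
       linear = list(
         fit = function(x, y, seed) list(fit = stats::lm.fit(cbind(1, x), y)),
         predict = function(m, x) as.vector(cbind(1, x) %*% m$fit$coefficients)))
}

toy_partition <- function(ids, seed = 1) {
  pat <- list(train_ids = ids, class_labels = NULL,
              regression_strata = stats::setNames(rep(1L, length(ids)), ids))
  rg <- regression_partition(pat, seed)
  c(pat, rg, list(test_ids = character()))
}

test_that("combine_features appends exactly one untouched probability column", {
  withr::with_seed(2, {
    x <- matrix(stats::rnorm(100 * 50), 100, 50,
                dimnames = list(sprintf("m%03d", 1:100), sprintf("d%02d", 1:50)))
    y <- stats::setNames(stats::rnorm(100), rownames(x))
    fm <- feature_matrix(x, y)
    p <- stats::setNames(stats::runif(100), rownames(x))
    comb <- combine_features(fm, p)
    expect_equal(ncol(comb$x), 51L)
    expect_equal(colnames(comb$x)[51L], "deepsnap_probability")
    # descriptor block bit-identical
    expect_identical(comb$x[, 1:50], fm$x)

    # a constant probability column is appended anyway
    comb2 <- combine_features(fm, stats::setNames(rep(0.5, 100), rownames(x)))
    expect_equal(unname(comb2$x[, 51L]), rep(0.5, 100))

    expect_error(combine_features(fm, p[-1L]), "missing probability")
  })
})

test_that("the competition picks the lowest CV RMSE with registry-order ties", {
  withr::with_seed(10, {
    n <- 120
    x <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(sprintf("c%03d", 1:n), c("f1", "f2", "f3")))
    y <- stats::setNames(2 * x[, 1] - x[, 2] + 0.5 * x[, 3] +
                           stats::rnorm(n, 0, 0.05), rownames(x))
    fm <- feature_matrix(x, y)
    part <- toy_partition(rownames(x))
    res <- run_competition(fm, part, toy_registry(), seed = 5)
    # linear recovery beats the mean predictors; chosen = exhaustive argmin
    expect_equal(res$chosen, "linear")
    expect_equal(res$chosen,
                 res$cv_table$algorithm[which.min(res$cv_table$cv_rmse)])
    expect_lt(res$metrics$rmse[res$metrics$set == "holdout"], 0.2)

    # two identical entrants tie -> first registry position wins
    res_tie <- run_competition(fm, part, toy_registry()[c("mean_a", "mean_b")],
                               seed = 5)
    expect_equal(res_tie$chosen, "mean_a")
  })
})

test_that("a constant target gives noise-level RMSE and no explanatory power", {
  withr::with_seed(11, {
    n <- 150; sd_noise <- 0.4
    x <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(sprintf("k%03d", 1:n), paste0("f", 1:4)))
    y <- stats::setNames(3 + stats::rnorm(n, 0, sd_noise), rownames(x))
    fm <- feature_matrix(x, y)
    res <- run_competition(fm, toy_partition(rownames(x)), toy_registry(), seed = 2)
    # closed form: predicting the mean of a pure-noise target leaves RMSE
    # at the noise SD
    expect_equal(res$metrics$rmse[res$metrics$set == "holdout"], sd_noise,
                 tolerance = 0.35)
    expect_lt(res$metrics$r2[res$metrics$set == "holdout"], 0.15)
  })
})

test_that("failing entrants are excluded and total failure errors", {
  withr::with_seed(3, {
    x <- matrix(stats::rnorm(80), 40, 2,
                dimnames = list(sprintf("e%02d", 1:40), c("a", "b")))
    y <- stats::setNames(x[, 1] + stats::rnorm(40, 0, 0.1), rownames(x))
    fm <- feature_matrix(x, y)
    part <- toy_partition(rownames(x))
    broken <- list(boom = list(fit = function(x, y, seed) stop("nope"),
                               predict = function(m, x) NULL))
    res <- run_competition(fm, part, c(broken, toy_registry()["linear"]), seed = 1)
    expect_equal(res$chosen, "linear")
    expect_error(run_competition(fm, part, broken, seed = 1), "all")
  })
})

test_that("real registry entrants fit and predict deterministically", {
  withr::with_seed(19, {
    n <- 90
    x <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(sprintf("q%03d", 1:n), paste0("f", 1:5)))
    y <- stats::setNames(x[, 1] - 2 * x[, 2] + stats::rnorm(n, 0, 0.2), rownames(x))
    fm <- feature_matrix(x, y)
    part <- toy_partition(rownames(x))
    reg <- default_algorithm_registry(c("elastic_net", "gradient_boosting"))
    r1 <- run_competition(fm, part, reg, seed = 7)
    r2 <- run_competition(fm, part, reg, seed = 7)
    expect_equal(r1$cv_table, r2$cv_table)
    expect_equal(r1$metrics, r2$metrics)
    expect_lt(r1$cv_table$cv_rmse[1L], stats::sd(y))  # better than the mean model
  })
})

test_that("ensemble averaging is the per-row mean of member predictions", {
  m1 <- list(entrant = list(predict = function(m, x) rep(1, nrow(x))), model = NULL)
  m2 <- list(entrant = list(predict = function(m, x) rep(3, nrow(x))), model = NULL)
  x <- matrix(0, 4, 2)
  expect_equal(ensemble_average(list(m1, m2), x), rep(2, 4))
  expect_equal(ensemble_average(list(m1, m1), x), rep(1, 4))
  expect_error(ensemble_average(list(m1), x), "two models")
  bad <- list(entrant = list(predict = function(m, x) 1), model = NULL)
  expect_error(ensemble_average(list(m1, bad), x), "mismatch")
})

test_that("ensembling never exceeds the worst member RMSE on synthetic data", {
  withr::with_seed(23, {
    n <- 100
    x <- matrix(stats::rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- x[, 1] + stats::rnorm(n, 0, 0.3)
    reg <- toy_registry()[c("mean_a", "linear")]
    fits <- lapply(reg, function(e) list(entrant = e, model = e$fit(x, y, 1)))
    ens <- ensemble_average(fits, x)
    worst <- max(vapply(fits, function(f)
      rmse(y, f$entrant$predict(f$model, x)), 0))
    expect_lte(rmse(y, ens), worst)
  })
})

test_that("permutation importance isolates the informative feature", {
  withr::with_seed(29, {
    n <- 200
    x <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("A", "B", "C")))
    y <- 3 * x[, "A"] + stats::rnorm(n, 0, 0.1)
    ent <- toy_registry()$linear
    model <- ent$fit(x[1:150, ], y[1:150], 1)
    imp <- permutation_importance(model, ent, x[151:200, ], y[151:200],
                                  n_repeats = 10, seed = 6)
    expect_equal(imp$normalized[imp$feature == "A"], 1)
    expect_lt(imp$normalized[imp$feature == "B"], 0.05)
    expect_lt(imp$normalized[imp$feature == "C"], 0.05)
    # determinism
    imp2 <- permutation_importance(model, ent, x[151:200, ], y[151:200],
                                   n_repeats = 10, seed = 6)
    expect_equal(imp, imp2)
    # a degenerate constant model has no usable importances
    const <- toy_registry()$mean_a
    cm <- const$fit(x[1:150, ], y[1:150], 1)
    expect_error(permutation_importance(cm, const, x[151:200, ], y[151:200],
                                        n_repeats = 2, seed = 1),
                 "degenerate")
  })
})

test_that("importance of an irrelevant feature vanishes as repeats grow", {
  withr::with_seed(41, {
    n <- 300
    x <- matrix(stats::rnorm(n * 2), n, 2, dimnames = list(NULL, c("sig", "junk")))
    y <- x[, "sig"] + stats::rnorm(n, 0, 0.05)
    ent <- toy_registry()$linear
    model <- ent$fit(x[1:200, ], y[1:200], 1)
    vals <- vapply(c(2L, 30L), function(reps)
      permutation_importance(model, ent, x[201:300, ], y[201:300],
                             n_repeats = reps, seed = 9)$raw[2L], 0)
    expect_lt(vals[2L], 0.02)
  })
})

test_that("average effect follows the stated imputation and sorting rules", {
  tab <- function(feats, vals)
    structure(data.frame(feature = feats, raw = vals, normalized = vals),
              class = c("importance_table", "data.frame"))
  five <- lapply(1:5, function(i) tab(c("top", "other"), c(1, 0.3)))
  ae <- average_effect(five)
  expect_equal(ae$average_effect[ae$feature == "top"], 1)

  once <- c(list(tab(c("top", "other"), c(1, 0.2))),
            lapply(1:4, function(i) tab(c("top", "other"), c(0, 0.2))))
  ae2 <- average_effect(once)
  expect_equal(ae2$average_effect[ae2$feature == "top"], 0.2)

  # feature absent from 2 of 5 patterns, scoring 0.5 elsewhere -> 0.3
  mixed <- c(lapply(1:3, function(i) tab(c("x", "y"), c(0.5, 1))),
             lapply(1:2, function(i) tab("y", 1)))
  ae3 <- average_effect(mixed)
  expect_equal(ae3$average_effect[ae3$feature == "x"], 0.3)
  # descending order
  expect_true(all(diff(ae3$average_effect) <= 0))
})
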