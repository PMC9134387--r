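test_that("the 1545-compound split reproduces the canonical cardinalities", {
  ids <- sprintf("c%04d", 1:1545)
  labels <- rep(0:1, length.out = 1545)
  plan <- make_split_plan(ids, labels, seed = 7)
  expect_equal(unname(as.vector(table(plan$folds))), rep(309L, 5L))
  for (p in plan$patterns) {
    expect_length(p$train_ids, 1236L)
    expect_length(p$test_ids, 309L)
    expect_length(p$deepsnap_train_ids, 927L)
    expect_length(p$deepsnap_val_ids, 309L)
    expect_length(p$regression_holdout_ids, 247L)   # round(0.2 * 1236)
    expect_length(p$regression_fit_ids, 989L)
    cv_sizes <- as.vector(table(p$cv_assignment))
    expect_true(max(cv_sizes) - min(cv_sizes) <= 1L)
  }
})

test_that("tiny libraries split evenly", {
  plan <- make_split_plan(sprintf("x%02d", 1:10), rep(0:1, 5), seed = 1)
  expect_equal(unname(as.vector(table(plan$folds))), rep(2L, 5L))
})

test_that("plans are deterministic in the seed and change with it", {
  ids <- sprintf("c%03d", 1:120)
  labels <- rep(0:1, 60)
  p1 <- make_split_plan(ids, labels, seed = 3)
  p2 <- make_split_plan(ids, labels, seed = 3)
  expect_identical(p1, p2)
  p3 <- make_split_plan(ids, labels, seed = 4)
  expect_false(identical(p1$folds, p3$folds))
})

test_that("partition and stratification properties hold over random cases", {
  withr::with_seed(99, {
    for (case in 1:6) {
      n <- sample(60:400, 1L)
      ids <- sprintf("r%04d", seq_len(n))
      labels <- stats::rbinom(n, 1L, stats::runif(1, 0.3, 0.7))
      if (length(unique(labels)) < 2L) labels[1:6] <- rep(0:1, 3)
      plan <- make_split_plan(ids, labels, seed = case)

      # folds partition the ids with sizes within 1
      expect_setequal(names(plan$folds), ids)
      fs <- table(plan$folds)
      expect_lte(max(fs) - min(fs), 1L)

      # every compound tested exactly once across patterns
      test_all <- unlist(lapply(plan$patterns, `[[`, "test_ids"))
      expect_setequal(test_all, ids)
      expect_false(any(duplicated(test_all)))

      glob <- mean(labels)
      names(labels) <- ids
      for (p in plan$patterns) {
        expect_setequal(c(p$train_ids, p$test_ids), ids)
        expect_length(intersect(p$deepsnap_train_ids, p$deepsnap_val_ids), 0L)
        expect_setequal(c(p$deepsnap_train_ids, p$deepsnap_val_ids), p$train_ids)
        # 3:1 within one compound
        expect_lte(abs(length(p$deepsnap_train_ids) - 3 * length(p$deepsnap_val_ids)), 3)
        expect_setequal(c(p$regression_fit_ids, p$regression_holdout_ids), p$train_ids)
        expect_length(intersect(p$regression_holdout_ids,
                                names(p$cv_assignment)), 0L)
        expect_equal(length(p$regression_holdout_ids),
                     round(0.2 * length(p$train_ids)), tolerance = 1)
        # stratified class fraction within 1/|part| of the global fraction
        for (part in list(p$deepsnap_train_ids, p$deepsnap_val_ids,
                          p$regression_holdout_ids))
          expect_lte(abs(mean(labels[part]) - glob), 1 / length(part) + 1e-9)
      }
    }
  })
})

test_that("allocation is exact for arbitrary strata shapes", {
  withr::with_seed(17, {
    for (case in 1:60) {
      k <- sample(2:6, 1L)
      n <- sample(11:200, 1L)
      n_strata <- sample(1:8, 1L)
      labels <- sample(letters[seq_len(n_strata)], n, replace = TRUE)
      ids <- sprintf("a%04d", seq_len(n))
      fr <- stats::runif(k, 0.2, 1)
      expect_no_warning(a <- stratified_allocate(ids, labels, fr, seed = case))
      expect_length(a, n)
      # part totals follow the largest-remainder rule
      fr_n <- fr / sum(fr)
      tot <- floor(n * fr_n)
      rem <- n * fr_n - tot
      extra <- order(-rem, seq_len(k))[seq_len(n - sum(tot))]
      tot[extra] <- tot[extra] + 1L
      expect_equal(unname(tabulate(a, k)), unname(as.integer(tot)))
      # per-stratum proportions within one compound of proportional
      for (s in unique(labels)) {
        ns <- sum(labels == s)
        if (ns < k) next
        got <- tabulate(a[labels == s], k)
        expect_true(all(abs(got - ns * fr_n) <= 1 + 1e-9))
      }
    }
  })
})

test_that("small strata fall back to pooled unstratified assignment", {
  ids <- sprintf("s%02d", 1:40)
  labels <- c(rep("big", 37L), "rare1", "rare2", "rare3")
  a <- stratified_allocate(ids, labels, rep(1, 5L), seed = 2)
  expect_equal(unname(as.vector(table(a))), rep(8L, 5L))
})

test_that("split plans round-trip through the text serialization", {
  ids <- sprintf("c%03d", 1:100)
  labels <- rep(0:1, 50)
  plan <- make_split_plan(ids, labels, seed = 12)
  f <- tempfile(fileext = ".tsv")
  write_split_plan(plan, f)
  back <- read_split_plan(f)
  expect_equal(back$folds, plan$folds)
  for (p in 1:5) {
    expect_setequal(back$patterns[[p]]$deepsnap_train_ids,
                    plan$patterns[[p]]$deepsnap_train_ids)
    expect_setequal(back$patterns[[p]]$regression_holdout_ids,
                    plan$patterns[[p]]$regression_holdout_ids)
    expect_equal(back$patterns[[p]]$cv_assignment[names(plan$patterns[[p]]$cv_assignment)],
                 plan$patterns[[p]]$cv_assignment)
  }
})

test_that("quantile bins are balanced and deterministic", {
  x <- stats::rnorm(103)
  b <- endpoint_quantile_bins(x)
  expect_equal(sort(unique(b)), 1:5)
  expect_lte(max(table(b)) - min(table(b)), 1L)
  expect_identical(b, endpoint_quantile_bins(x))
})
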