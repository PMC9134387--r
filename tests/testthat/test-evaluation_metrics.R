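test_that("rmse matches its closed form and is homogeneous", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  a <- c(0.3, -1.2, 2.5); b <- c(1.1, 0.4, -0.7)
  expect_equal(rmse(3.7 * a, 3.7 * b), 3.7 * rmse(a, b))
  expect_error(rmse(1:3, 1:2))
  expect_error(rmse(numeric(), numeric()))
})

test_that("the two R-squared variants behave per their definitions", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  expect_equal(r_squared(x, x), 1)
  # anti-correlated predictions: squared Pearson stays 1, determination <= 0
  expect_equal(r_squared(x, -x, method = "pearson"), 1)
  expect_lte(r_squared(x, -x, method = "determination"), 0)
  v <- r_squared(x, -x, verbose = TRUE)
  expect_named(v, c("pearson", "determination"))
  expect_error(r_squared(rep(1, 5), x), "constant")

  withr::with_seed(8, {
    a <- stats::rnorm(1e4); b <- stats::rnorm(1e4)
    expect_lt(r_squared(a, b), 0.01)
  })
})

test_that("metric kernels agree with brute-force reimplementations", {
  withr::with_seed(21, {
    for (i in 1:5) {
      a <- stats::rnorm(50); b <- stats::rnorm(50)
      expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 50), tolerance = 1e-12)
      expect_equal(r_squared(a, b),
                   (sum((a - mean(a)) * (b - mean(b))) /
                      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2,
                   tolerance = 1e-12)
    }
  })
})

test_that("auc equals the exhaustive pair count and honors tie/monotone rules", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  labels <- c(1, 0, 1, 0); scores <- c(0.9, 0.8, 0.7, 0.1)
  # oracle: enumerate all positive-negative pairs
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(auc(labels, scores), wins / (length(pos) * length(neg)))
  expect_equal(auc(labels, scores), 0.75)
  # invariance under strictly monotone transforms
  expect_equal(auc(labels, scores), auc(labels, exp(5 * scores)))
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")

  withr::with_seed(14, {
    l <- stats::rbinom(60, 1, 0.5); s <- stats::rnorm(60)
    expect_equal(auc(l, s), as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                           direction = "<"))))
  })
})

test_that("pca_space standardizes, orders variance and keeps scores orthogonal", {
  withr::with_seed(5, {
    n <- 80
    base <- stats::rnorm(n)
    d <- data.frame(a = base, b = 2 * base + 1, c = -base)
    rank1 <- pca_space(d, c("a", "b", "c"))
    expect_equal(rank1$variance_fraction[1L], 1, tolerance = 1e-9)

    d2 <- as.data.frame(matrix(stats::rnorm(n * 5), n))
    names(d2) <- letters[1:5]
    p <- pca_space(d2, letters[1:5], fold_assignment = rep(1:5, each = 16))
    expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
    expect_true(all(diff(p$variance_fraction) <= 1e-12))
    sc <- as.matrix(p$scores[, c("PC1", "PC2", "PC3")])
    cc <- stats::cor(sc)
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-9)
    expect_error(pca_space(d2, c("a", "nope")), "absent")
    d2$flat <- 1
    expect_error(pca_space(d2, c("a", "flat")), "constant")
  })
})

test_that("folds drawn from one distribution overlap in PC space", {
  withr::with_seed(31, {
    n <- 200
    d <- as.data.frame(matrix(stats::rnorm(n * 4), n))
    names(d) <- c("w", "x", "y", "z")
    fold <- rep(1:5, each = 40)
    p <- pca_space(d, names(d), fold)
    pc1 <- p$scores$PC1
    mu <- tapply(pc1, fold, mean)
    expect_lt(max(mu) - min(mu), 0.5 * stats::sd(pc1))
  })
})
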