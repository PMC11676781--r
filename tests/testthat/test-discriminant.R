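test_that("univariate Wilks' lambda covers the textbook cases", {
  # equal group means: no between-group separation
  expect_equal(
    wilks_univariate(c(1, 3, 1, 3, 1, 3),
                     c("a", "a", "b", "b", "c", "c"))$lambda, 1
  )
  # distinct means, zero within-group variance
  expect_equal(
    wilks_univariate(c(1, 1, 2, 2, 3, 3),
                     c("a", "a", "b", "b", "c", "c"))$lambda, 0
  )
  # direct summation: SSW = 1, SSTOT = 5
  res <- wilks_univariate(c(0, 1, 2, 3), c("a", "a", "b", "b"))
  expect_equal(res$lambda, 1 / 5)
  expect_equal(res$ssw, 1)
  expect_equal(res$sstot, 5)
  expect_error(wilks_univariate(c(1, 1, 1, 1), c("a", "a", "b", "b")),
               "zero")
  expect_error(wilks_univariate(1:4, rep("a", 4)), "2 groups")
})

test_that("multivariate lambda reduces to the univariate one at p = 1", {
  set.seed(21)
  x <- rnorm(18)
  labels <- rep(c("a", "b", "c"), each = 6)
  expect_equal(wilks_multivariate(matrix(x), labels)$lambda,
               wilks_univariate(x, labels)$lambda, tolerance = 1e-12)
})

test_that("wilks statistics match brute-force oracles on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n_per <- sample(4:10, 3, replace = TRUE)
    p <- sample(1:4, 1)
    labels <- rep(c("a", "b", "c"), n_per)
    x <- matrix(rnorm(sum(n_per) * p), sum(n_per), p) +
      matrix(rep(rnorm(3, sd = 2), n_per), sum(n_per), p)
    expect_equal(wilks_multivariate(x, labels)$lambda,
                 oracle_wilks_multi(x, labels),
                 tolerance = 1e-10)
    expect_equal(wilks_univariate(x[, 1], labels)$lambda,
                 oracle_wilks_uni(x[, 1], labels),
                 tolerance = 1e-10)
  }
})

test_that("adding a variable never increases the multivariate lambda", {
  set.seed(55)
  for (i in 1:20) {
    labels <- rep(c("a", "b", "c"), each = 8)
    x <- matrix(rnorm(24 * 4), 24, 4)
    for (p in 2:4) {
      expect_lte(
        wilks_multivariate(x[, 1:p], labels)$lambda,
        wilks_multivariate(x[, 1:(p - 1), drop = FALSE], labels)$lambda +
          1e-12
      )
    }
  }
})

test_that("collinear variables make the total scatter singular", {
  labels <- rep(c("a", "b", "c"), each = 5)
  x <- matrix(rnorm(15 * 2), 15, 2)
  expect_error(wilks_multivariate(cbind(x, x[, 1]), labels), "singular")
})

test_that("the partial F test matches its closed form", {
  expect_equal(partial_f_test(0.5, 0.5, 30, 3, 2)$statistic, 0)
  # halving lambda_with takes (ratio - 1) from 1 to 3
  f1 <- partial_f_test(0.25, 0.5, 30, 3, 2)$statistic
  f2 <- partial_f_test(0.125, 0.5, 30, 3, 2)$statistic
  expect_equal(f2 / f1, 3)
  # explicit arithmetic: I=30, G=3, p=2 -> factor 25/2
  res <- partial_f_test(0.4, 0.6, 30, 3, 2)
  expect_equal(res$statistic, (25 / 2) * (0.6 / 0.4 - 1), tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(2, 25))
  expect_equal(res$p_value, pf(res$statistic, 2, 25, lower.tail = FALSE))
  expect_error(partial_f_test(0.4, 0.6, 5, 3, 2), "> 0")
  expect_error(partial_f_test(0.7, 0.6, 30, 3, 2), "lambda")
})

test_that("a 3-class model on p >= 2 variables has two canonical variates", {
  blobs <- make_blobs(n_per_class = 8, p = 4)
  fit <- lda_fit(make_wide(blobs$x, blobs$labels))
  expect_equal(ncol(fit$directions), 2)
  expect_equal(length(fit$classes), 3)
  # within-class variance along each direction is 1
  for (j in 1:2) {
    a <- fit$directions[, j]
    expect_equal(drop(t(a) %*% fit$pooled_cov %*% a), 1,
                 tolerance = 1e-10)
  }
})

test_that("far-separated spherical classes classify perfectly", {
  blobs <- make_blobs(n_per_class = 10, p = 3, sep = 30)
  wide <- make_wide(blobs$x, blobs$labels)
  fit <- lda_fit(wide)
  expect_equal(classification_rate(predict(fit, wide), blobs$labels), 100)
  # training class means project onto their own classes
  means_wide <- dplyr::bind_cols(
    tibble::tibble(class = rownames(fit$means)),
    tibble::as_tibble(fit$means)
  )
  expect_equal(predict(fit, means_wide), rownames(fit$means))
})

test_that("two-class prediction equals the closed-form linear rule", {
  set.seed(12)
  n <- 40
  x <- rbind(
    matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, 0.4, 0.4, 1), 2)),
    sweep(matrix(rnorm(n * 2), n, 2) %*%
            chol(matrix(c(1, 0.4, 0.4, 1), 2)), 2, c(2.5, 1), "+")
  )
  colnames(x) <- c("v1", "v2")
  labels <- rep(c("a", "b"), each = n)
  wide <- make_wide(x, labels)
  fit <- lda_fit(wide)
  # Bayes rule for equal-covariance Gaussians with equal priors:
  # assign "a" iff w'(x - (m_a + m_b)/2) > 0 with w = S^-1 (m_a - m_b)
  w <- solve(fit$pooled_cov, fit$means["a", ] - fit$means["b", ])
  mid <- (fit$means["a", ] + fit$means["b", ]) / 2
  closed <- ifelse(sweep(x, 2, mid) %*% w > 0, "a", "b")
  expect_equal(predict(fit, wide), as.character(closed))
})

test_that("predictions agree with an established LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(202)
  for (i in 1:10) {
    blobs <- make_blobs(n_per_class = 12, p = sample(2:4, 1),
                        sep = runif(1, 2, 6), seed = 300 + i)
    wide <- make_wide(blobs$x, blobs$labels)
    fit <- lda_fit(wide)
    ref <- MASS::lda(blobs$x, grouping = blobs$labels,
                     prior = rep(1 / 3, 3))
    expect_equal(predict(fit, wide),
                 as.character(predict(ref, blobs$x)$class))
  }
})

test_that("canonical projection is the advertised linear map", {
  blobs <- make_blobs(n_per_class = 9, p = 3, sep = 8)
  wide <- make_wide(blobs$x, blobs$labels)
  fit <- lda_fit(wide)
  proj <- project_canonical(fit, wide)
  manual <- sweep(blobs$x, 2, fit$grand_mean) %*% fit$directions
  expect_equal(as.matrix(proj[, c("CV1", "CV2")]), manual,
               ignore_attr = TRUE, tolerance = 1e-12)
  # linearity: the projection of a class mean is the mean projection
  mean_a <- colMeans(blobs$x[blobs$labels == "a", ])
  proj_mean <- (mean_a - fit$grand_mean) %*% fit$directions
  expect_equal(drop(proj_mean),
               colMeans(manual[blobs$labels == "a", ]),
               tolerance = 1e-12)
  expect_error(
    project_canonical(fit, dplyr::rename(wide, z1 = "v1")),
    "not present"
  )
})

test_that("canonical-variate geometry agrees with the Mahalanobis rule", {
  # on a well-conditioned toy, nearest class mean in CV space (all G-1
  # variates) must give the same assignments as the pooled-covariance rule
  blobs <- make_blobs(n_per_class = 15, p = 3, sep = 4, seed = 91)
  wide <- make_wide(blobs$x, blobs$labels)
  fit <- lda_fit(wide)
  proj <- as.matrix(project_canonical(fit, wide)[, c("CV1", "CV2")])
  mean_proj <- sweep(fit$means, 2, fit$grand_mean) %*% fit$directions
  nearest <- fit$classes[apply(proj, 1, function(z) {
    which.min(colSums((t(mean_proj) - z)^2))
  })]
  expect_equal(nearest, predict(fit, wide))
})

test_that("classification rates count correct assignments in percent", {
  truth <- rep(c("a", "b"), each = 5)
  pred <- truth
  pred[1] <- "b"
  expect_equal(classification_rate(pred, truth), 90)
  rates <- classification_rates(pred, truth)
  expect_equal(rates$rate_pct[rates$class == "a"], 80)
  expect_equal(rates$rate_pct[rates$class == "total"], 90)
  expect_error(classification_rate(character(0), character(0)), "nonempty")
})

test_that("degenerate LDA inputs raise explicit errors", {
  blobs <- make_blobs(n_per_class = 5, p = 2)
  wide <- make_wide(blobs$x, blobs$labels)
  dup <- dplyr::mutate(wide, v3 = .data$v1)
  expect_error(lda_fit(dup), "singular")
  expect_error(lda_fit(wide[c(1, 6, 7, 11, 12), ]), "at least 2")
  expect_error(lda_fit(wide, priors = c(a = 0.5, b = 0.6, c = 0.1)),
               "sum to 1")
})
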