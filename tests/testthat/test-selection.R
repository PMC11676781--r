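test_that("fold plans partition the samples with stratification", {
  labels <- rep(c("a", "b", "c"), c(24, 24, 28))
  folds <- make_folds(labels, k = 7, seed = 3)
  expect_setequal(folds$index, seq_along(labels))
  expect_equal(sort(unique(folds$fold)), 1:7)
  # per-class fold counts differ by at most one sample
  per <- table(folds$class, folds$fold)
  expect_true(all(apply(per, 1, function(r) diff(range(r)) <= 1)))
  # deterministic given seed
  expect_identical(folds, make_folds(labels, k = 7, seed = 3))
  expect_false(identical(folds$fold,
                         make_folds(labels, k = 7, seed = 4)$fold))
})

test_that("leave-one-out and degenerate fold requests behave", {
  labels <- rep(c("a", "b"), each = 4)
  expect_warning(loo <- make_folds(labels, k = 8, seed = 1), "relaxed")
  expect_equal(sort(loo$fold), 1:8)
  expect_error(make_folds(labels, k = 9, seed = 1), "exceed")
  expect_error(make_folds(labels, k = 1, seed = 1), "at least 2")
})

test_that("dummy coding yields centred per-class indicators", {
  labels <- rep(c("a", "b", "c"), times = c(3, 4, 5))
  y <- dummy_code(labels)
  expect_equal(dim(y), c(12, 3))
  expect_equal(colnames(y), c("a", "b", "c"))
  expect_equal(unname(colSums(y)), rep(0, 3), tolerance = 1e-14)
  # adding back the column means recovers 0/1 indicators with unit row sums
  raw <- sweep(y, 2, attr(y, "scaled:center"), "+")
  expect_true(all(raw %in% c(0, 1)))
  expect_equal(unname(rowSums(raw)), rep(1, 12))
  # two classes: centred indicators are +/- constants
  y2 <- dummy_code(rep(c("a", "b"), c(2, 6)))
  expect_equal(sort(unique(y2[, "a"])), c(-0.25, 0.75))
  expect_error(dummy_code(rep("a", 5)), "2 classes")
})

test_that("the first CovSel pick maximizes summed squared covariance", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(12:30, 1)
    p <- sample(2:10, 1)
    labels <- sample(c("a", "b", "c"), n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.4))
    if (length(unique(labels)) < 3) next
    x <- scale(matrix(rnorm(n * p), n, p))
    y <- dummy_code(labels)
    expect_equal(unname(covsel_order(x, y)[1]),
                 unname(oracle_covsel_first(x, y)))
  }
})

test_that("deflation removes duplicated information", {
  set.seed(23)
  x <- scale(matrix(rnorm(20 * 4), 20, 4))
  x <- cbind(x, x[, 1]) # column 5 duplicates column 1
  y <- dummy_code(rep(c("a", "b"), each = 10))
  ord <- covsel_order(x, y)
  first <- ord[1]
  if (first %in% c(1, 5)) {
    # the duplicate's deflated covariance is 0: never picked second
    expect_false(ord[2] %in% c(1, 5))
  }
  # single-variable input returns that variable
  expect_equal(unname(covsel_order(x[, 1, drop = FALSE], y)), 1)
})

test_that("on orthonormal predictors CovSel sorts by squared covariance", {
  set.seed(41)
  for (i in 1:10) {
    n <- 24
    p <- sample(3:6, 1)
    # orthonormal columns of the centred span: centring preserves them
    x <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), center = TRUE,
                       scale = FALSE)))
    y <- dummy_code(rep(c("a", "b", "c"), each = 8))
    scores <- apply(x, 2, function(xj) {
      sum(apply(y, 2, function(yg) cov(xj, yg))^2)
    })
    expect_equal(unname(covsel_order(x, y)), order(scores,
                                                   decreasing = TRUE))
  }
})

test_that("a single separating variable is selected alone", {
  set.seed(61)
  n_per <- 12
  labels <- rep(c("a", "b", "c"), each = n_per)
  x <- cbind(
    sep = rep(c(-8, 0, 8), each = n_per) + rnorm(3 * n_per, 0, 0.3),
    noise1 = rnorm(3 * n_per),
    noise2 = rnorm(3 * n_per)
  )
  wide <- make_wide(scale(x), labels)
  sel <- covsel_select(wide, k = 4, seed = 2)
  expect_equal(sel$final_size, 1)
  expect_equal(sel$final_elements, "sep")
})

test_that("classes separable only jointly need two variables", {
  # class means at (0,0), (6,0), (0,6): neither axis separates all three
  set.seed(62)
  n_per <- 12
  labels <- rep(c("a", "b", "c"), each = n_per)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  x <- centers[rep(1:3, each = n_per), ] +
    matrix(rnorm(3 * n_per * 2, 0, 0.5), 3 * n_per, 2)
  colnames(x) <- c("d1", "d2")
  wide <- make_wide(scale(x), labels)
  sel <- covsel_select(wide, k = 4, seed = 5)
  expect_equal(sel$final_size, 2)
  expect_setequal(sel$final_elements, c("d1", "d2"))
})

test_that("selection results are deterministic given the seed", {
  tbl <- simulate_flours(seed = 3)
  scaled <- conc_widen(autoscale_apply(tbl, autoscale_fit(tbl)))
  scaled <- scaled[, names(scaled) != "10B"]
  a <- covsel_select(scaled, seed = 10)
  b <- covsel_select(scaled, seed = 10)
  expect_identical(a$final_elements, b$final_elements)
  expect_identical(a$cv_curve, b$cv_curve)
  s1 <- stepwise_wilks(scaled, seed = 10)
  s2 <- stepwise_wilks(scaled, seed = 10)
  expect_identical(s1$final_elements, s2$final_elements)
  expect_identical(s1$per_fold, s2$per_fold)
})

test_that("stepwise enters the lowest univariate lambda first", {
  set.seed(71)
  n_per <- 10
  labels <- rep(c("a", "b", "c"), each = n_per)
  x <- cbind(
    strong = rep(c(-6, 0, 6), each = n_per) + rnorm(3 * n_per, 0, 0.4),
    weak = rep(c(-1, 0, 1), each = n_per) + rnorm(3 * n_per),
    noise = rnorm(3 * n_per)
  )
  wide <- make_wide(scale(x), labels)
  sel <- stepwise_wilks(wide, k = 3, seed = 4)
  uni <- vapply(c("strong", "weak", "noise"), function(el) {
    wilks_univariate(wide[[el]], labels)$lambda
  }, numeric(1))
  expect_equal(names(which.min(uni)), "strong")
  for (fold_sel in sel$per_fold) expect_equal(fold_sel[1], "strong")
  # stepwise never selects the same variable twice
  for (fold_sel in sel$per_fold) {
    expect_equal(anyDuplicated(fold_sel), 0)
  }
})

test_that("a pure-noise companion fails the F-to-enter gate", {
  # one variable separates the classes cleanly; the second is independent
  # standard normal. With alpha = 0.05 the selection stops at size 1.
  set.seed(83)
  n_per <- 14
  labels <- rep(c("a", "b", "c"), each = n_per)
  x <- cbind(
    signal = rep(c(-10, 0, 10), each = n_per) + rnorm(3 * n_per, 0, 0.5),
    noise = rnorm(3 * n_per)
  )
  wide <- make_wide(scale(x), labels)
  sel <- stepwise_wilks(wide, k = 3, alpha = 0.05, seed = 6)
  expect_equal(sel$final_elements, "signal")
  expect_true(all(vapply(sel$per_fold, identical, logical(1), "signal")))
})

test_that("univariate discrimination tracks relative class-mean spread", {
  # with one shared cv, elements whose class means differ by several
  # within-class sds (Mn: 46.6/6.6/13.4) must rank far above elements
  # with identical class means (Ni: 0.6 everywhere, lambda near 1)
  tbl <- simulate_flours(seed = 1)
  scaled <- conc_widen(autoscale_apply(tbl, autoscale_fit(tbl)))
  lam <- function(el) wilks_univariate(scaled[[el]], scaled$class)$lambda
  expect_lt(lam("55Mn"), 0.1)
  expect_gt(lam("60Ni"), 0.8)
  expect_lt(lam("55Mn"), lam("24Mg"))
})

test_that("frequency aggregation ranks by count with stable tie-breaks", {
  ranked <- aggregate_frequencies(
    list(c("A", "B"), "A", c("A", "C")),
    levels = c("A", "B", "C")
  )
  expect_equal(ranked$variable, c("A", "B", "C"))
  expect_equal(ranked$count, c(3L, 1L, 1L))
  # tie values override the index order
  ranked2 <- aggregate_frequencies(
    list(c("A", "B"), "A", c("A", "C")),
    levels = c("A", "B", "C"), tie_values = c(A = 0.1, B = 0.9, C = 0.2)
  )
  expect_equal(ranked2$variable, c("A", "C", "B"))
  # identical selections in every fold: that set, original order
  same <- aggregate_frequencies(list(c("B", "A"), c("B", "A")),
                                levels = c("A", "B"))
  expect_equal(same$variable, c("A", "B"))
  expect_equal(same$count, c(2L, 2L))
  # a single fold is returned verbatim
  single <- aggregate_frequencies(list(c("C", "A")),
                                  levels = c("A", "B", "C"))
  expect_setequal(single$variable, c("A", "C"))
  expect_error(aggregate_frequencies(list()), "at least one")
})
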