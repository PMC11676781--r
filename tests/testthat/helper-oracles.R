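# Independent brute-force oracles and small data builders used across the
# suite. The oracles deliberately use naive elementwise summation, never
# the package's own matrix code paths.

# Univariate Wilks' lambda by direct summation.
oracle_wilks_uni <- function(x, labels) {
  ssw <- 0
  for (grp in unique(labels)) {
    xi <- x[labels == grp]
    ssw <- ssw + sum((xi - mean(xi))^2)
  }
  ssw / sum((x - mean(x))^2)
}

# Multivariate Wilks' lambda via explicitly accumulated scatter matrices
# and determinants.
oracle_wilks_multi <- function(x, labels) {
  x <- as.matrix(x)
  p <- ncol(x)
  w <- matrix(0, p, p)
  for (grp in unique(labels)) {
    xg <- x[labels == grp, , drop = FALSE]
    m <- colMeans(xg)
    for (i in seq_len(nrow(xg))) {
      d <- xg[i, ] - m
      w <- w + outer(d, d)
    }
  }
  tt <- matrix(0, p, p)
  m_all <- colMeans(x)
  for (i in seq_len(nrow(x))) {
    d <- x[i, ] - m_all
    tt <- tt + outer(d, d)
  }
  det(w) / det(tt)
}

# Exhaustive first CovSel pick: argmax_j of sum_g cov(x_j, y_g)^2.
oracle_covsel_first <- function(x, y) {
  scores <- apply(x, 2, function(xj) {
    sum(apply(y, 2, function(yg) cov(xj, yg))^2)
  })
  which.max(scores)
}

# Long concentration table from a wide numeric matrix.
make_conc <- function(values, classes, elements = colnames(values),
                      flags = NULL) {
  wide <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(values))),
    class = classes
  )
  wide <- dplyr::bind_cols(
    wide, tibble::as_tibble(`colnames<-`(values, elements))
  )
  long <- conc_lengthen(wide)
  if (!is.null(flags)) long$flag <- flags
  long
}

# Three well-separated spherical Gaussian classes in p dimensions.
make_blobs <- function(n_per_class = 10, p = 2, sep = 10, sd = 1,
                       seed = 42) {
  centers <- diag(sep, 3, p)
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(g) {
      matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p) +
        matrix(centers[g, ], n_per_class, p, byrow = TRUE)
    }))
  })
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, labels = rep(c("a", "b", "c"), each = n_per_class))
}

# Wide tibble (class + predictors) from a matrix and labels.
make_wide <- function(x, labels) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(nrow(x))),
                   class = labels),
    tibble::as_tibble(x)
  )
}
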