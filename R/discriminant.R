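#' Univariate Wilks' lambda
#'
#' `lambda = SSW / SSTOT`: the within-group sum of squares over the total
#' sum of squares. Values near 0 mean the groups are well separated on
#' this variable; 1 means no between-group structure.
#'
#' @param x Numeric vector.
#' @param labels Group labels, at least 2 groups with >= 1 member each.
#' @return One-row tibble: `lambda`, `ssw`, `sstot`, `n`, `g`.
#' @export
#' @examples
#' wilks_univariate(c(0, 1, 2, 3), c("a", "a", "b", "b")) # lambda 1/5
wilks_univariate <- function(x, labels) {
  if (length(x) != length(labels)) {
    abort("`x` and `labels` must have the same length.")
  }
  labels <- as.character(labels)
  groups <- unique(labels)
  g <- length(groups)
  n <- length(x)
  if (g < 2) abort("Wilks' lambda needs at least 2 groups.")
  if (n < g + 1) abort("Need more samples than groups.")
  sstot <- sum((x - mean(x))^2)
  if (sstot == 0) abort("Total variance is zero; lambda is undefined.")
  ssw <- sum(vapply(groups, function(grp) {
    xi <- x[labels == grp]
    sum((xi - mean(xi))^2)
  }, numeric(1)))
  tibble::tibble(lambda = ssw / sstot, ssw = ssw, sstot = sstot,
                 n = n, g = g)
}

# within (W) and total (T) scatter matrices about group/grand means
scatter_matrices <- function(x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  groups <- unique(labels)
  centred_total <- sweep(x, 2, colMeans(x))
  t_scatter <- crossprod(centred_total)
  w_scatter <- matrix(0, ncol(x), ncol(x))
  for (grp in groups) {
    xg <- x[labels == grp, , drop = FALSE]
    cg <- sweep(xg, 2, colMeans(xg))
    w_scatter <- w_scatter + crossprod(cg)
  }
  list(w = w_scatter, t = t_scatter, n = nrow(x), g = length(groups),
       p = ncol(x), groups = groups)
}

#' Multivariate Wilks' lambda
#'
#' `lambda = det(W) / det(T)` where `W` is the pooled within-group scatter
#' and `T` the total scatter. Equivalently the ratio of determinants of the
#' pooled covariance `P = W / (I - G)` and the generalized covariance
#' `V = T / (I - 1)`, after normalizing each scatter by its degrees of
#' freedom (`I` samples, `G` classes). Reduces to [wilks_univariate()] for
#' a single variable.
#'
#' @param x Numeric matrix or data frame of predictors (samples x
#'   variables).
#' @param labels Group labels.
#' @return One-row tibble: `lambda`, `det_within`, `det_total`, `n`, `g`,
#'   `p`.
#' @export
wilks_multivariate <- function(x, labels) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) {
    abort("`x` rows and `labels` must match.")
  }
  sc <- scatter_matrices(x, labels)
  if (sc$n <= sc$g + sc$p) {
    abort("Need n > G + p samples for the multivariate lambda.")
  }
  det_t <- det(sc$t)
  scale_ref <- prod(diag(sc$t))
  if (!is.finite(det_t) || scale_ref == 0 ||
      abs(det_t) < 1e-12 * scale_ref) {
    abort("Total scatter matrix is singular (collinear variables).")
  }
  det_w <- det(sc$w)
  tibble::tibble(lambda = det_w / det_t, det_within = det_w,
                 det_total = det_t, n = sc$n, g = sc$g, p = sc$p)
}

#' Partial F test for adding one variable to a discriminant model
#'
#' Rao's one-variable-added approximation (exact for a single added
#' variable): with `p_current` variables already in the model,
#' `F = ((I - G - p_current) / (G - 1)) * (lambda_without / lambda_with - 1)`
#' on `(G - 1, I - G - p_current)` degrees of freedom. Used as the
#' F-to-enter test of the significance of the Wilks'-lambda decrease.
#'
#' @param lambda_with Multivariate lambda after adding the candidate.
#' @param lambda_without Lambda of the current model (1 for the empty
#'   model).
#' @param n Number of training samples `I`.
#' @param g Number of classes `G`.
#' @param p_current Number of variables already in the model (before the
#'   addition).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @export
partial_f_test <- function(lambda_with, lambda_without, n, g, p_current) {
  check_scalar_number(lambda_with, "lambda_with", positive = TRUE)
  check_scalar_number(lambda_without, "lambda_without", positive = TRUE)
  if (lambda_with > lambda_without + 1e-12 || lambda_without > 1 + 1e-12) {
    abort("Require 0 < lambda_with <= lambda_without <= 1.")
  }
  df2 <- n - g - p_current
  if (df2 <= 0) abort("Need n - G - p_current > 0 for the F test.")
  f_stat <- (df2 / (g - 1)) * (lambda_without / lambda_with - 1)
  tibble::tibble(
    statistic = f_stat, df1 = g - 1, df2 = df2,
    p_value = pf(f_stat, g - 1, df2, lower.tail = FALSE)
  )
}

#' Fit a linear discriminant model with canonical variates
#'
#' Classical LDA: per-class mean vectors, pooled within-class covariance
#' `P` (df `I - G`), generalized covariance `V` (df `I - 1`), and canonical
#' directions — the leading eigenvectors of `P^{-1} B` (`B` the
#' between-class scatter), scaled so the pooled within-class variance along
#' each direction is 1. A `G`-class model on `p` variables has
#' `min(G - 1, p)` canonical variates. Prediction assigns each sample to
#' the class minimizing the Mahalanobis distance under `P`, adjusted by
#' log-priors.
#'
#' @param data Wide tibble: `class` column plus one numeric column per
#'   predictor element (typically autoscaled training data).
#' @param elements Predictor columns to use; default all non-id columns.
#' @param priors `"equal"` (default), `"proportional"`, or a named numeric
#'   vector summing to 1.
#' @return An object of class `flda`; see [project_canonical()] and
#'   [predict.flda()]. `tidy()` and `glance()` methods are provided.
#' @export
#' @examples
#' tbl <- simulate_flours(seed = 1)
#' wide <- conc_widen(autoscale_apply(tbl, autoscale_fit(tbl)))
#' fit <- lda_fit(wide, elements = c("24Mg", "80Se"))
#' classification_rate(predict(fit, wide), wide$class)
lda_fit <- function(data, elements = NULL, priors = "equal") {
  if (!is.data.frame(data) || !"class" %in% names(data)) {
    abort("`data` must be a data frame with a `class` column.")
  }
  if (is.null(elements)) {
    elements <- setdiff(names(data), c("sample_id", "class"))
  }
  x <- wide_matrix(data, elements)
  labels <- as.character(data$class)
  counts <- table(labels)
  if (any(counts < 2)) abort("Every class needs at least 2 samples.")
  sc <- scatter_matrices(x, labels)
  groups <- sc$groups
  g <- sc$g
  p <- sc$p
  n <- sc$n

  pooled_cov <- sc$w / (n - g)
  total_cov <- sc$t / (n - 1)
  means <- matrix(
    vapply(groups, function(grp) {
      colMeans(x[labels == grp, , drop = FALSE])
    }, numeric(p)),
    nrow = g, ncol = p, byrow = TRUE,
    dimnames = list(groups, elements)
  )
  grand_mean <- colMeans(x)

  pr <- if (identical(priors, "equal")) {
    setNames(rep(1 / g, g), groups)
  } else if (identical(priors, "proportional")) {
    setNames(as.numeric(counts[groups]) / n, groups)
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), groups) ||
        abs(sum(priors) - 1) > 1e-8) {
      abort("Numeric `priors` must be named by class and sum to 1.")
    }
    priors[groups]
  }

  # canonical directions: eigenvectors of P^{-1} B via the symmetric
  # reduction with the Cholesky factor of P; a' P a = 1 by construction
  b_scatter <- sc$t - sc$w
  chol_p <- tryCatch(chol(pooled_cov), error = function(e) {
    abort("Pooled within-class covariance is singular on this subset.")
  })
  m_sym <- backsolve(chol_p, t(backsolve(chol_p, b_scatter,
                                         transpose = TRUE)),
                     transpose = TRUE)
  eig <- eigen((m_sym + t(m_sym)) / 2, symmetric = TRUE)
  r <- min(g - 1, p)
  directions <- backsolve(chol_p, eig$vectors[, seq_len(r), drop = FALSE])
  for (j in seq_len(r)) {
    # a' P a = 1 holds up to round-off; renormalize and fix the sign
    directions[, j] <- directions[, j] /
      sqrt(drop(t(directions[, j]) %*% pooled_cov %*% directions[, j]))
    i_max <- which.max(abs(directions[, j]))
    if (directions[i_max, j] < 0) directions[, j] <- -directions[, j]
  }
  rownames(directions) <- elements
  colnames(directions) <- paste0("CV", seq_len(r))

  structure(
    list(
      elements = elements, classes = groups, means = means,
      pooled_cov = pooled_cov, total_cov = total_cov,
      grand_mean = grand_mean, directions = directions,
      eigenvalues = eig$values[seq_len(r)], priors = pr, n = n,
      n_per_class = setNames(as.integer(counts[groups]), groups)
    ),
    class = "flda"
  )
}

#' @export
print.flda <- function(x, ...) {
  cat(sprintf(
    "Linear discriminant model: %d classes, %d predictor(s), %d samples\n",
    length(x$classes), length(x$elements), x$n
  ))
  cat("  predictors:", paste(x$elements, collapse = ", "), "\n")
  cat("  canonical variates:", ncol(x$directions), "\n")
  invisible(x)
}

#' @export
tidy.flda <- function(x, ...) {
  tibble::as_tibble(x$directions, rownames = "element") |>
    tidyr::pivot_longer(dplyr::starts_with("CV"),
                        names_to = "canonical_variate",
                        values_to = "coefficient")
}

#' @export
glance.flda <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_classes = length(x$classes),
    n_predictors = length(x$elements),
    n_canonical = ncol(x$directions)
  )
}

#' Project samples onto the canonical variates
#'
#' Scores are the (training-grand-mean-)centred data multiplied by the
#' canonical directions; within-class variance along each variate is 1 by
#' the model's normalization.
#'
#' @param model An `flda` object.
#' @param data Wide tibble carrying the model's predictor columns, already
#'   autoscaled with the training parameters.
#' @return Tibble: `sample_id` (if present), `class` (if present), `CV1`,
#'   `CV2`, ...
#' @export
project_canonical <- function(model, data) {
  if (!inherits(model, "flda")) abort("`model` must be an `flda` object.")
  x <- wide_matrix(data, model$elements)
  scores <- sweep(x, 2, model$grand_mean) %*% model$directions
  out <- tibble::as_tibble(scores)
  if ("class" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(class = data$class), out)
  }
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

#' Predict flour classes with a fitted discriminant model
#'
#' Assigns each sample to the class minimizing the Mahalanobis distance to
#' the class mean under the pooled within-class covariance, offset by the
#' log-prior — the linear (equal-covariance) discriminant rule.
#'
#' @param object An `flda` object.
#' @param newdata Wide tibble with the model's predictor columns (same
#'   autoscaling as training).
#' @param type `"class"` (default) for predicted labels, `"score"` for the
#'   per-class discriminant scores.
#' @param ... Unused.
#' @return Character vector of labels, or a tibble of scores.
#' @export
predict.flda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- wide_matrix(newdata, object$elements)
  if (nrow(x) == 0) abort("`newdata` has no rows.")
  pinv <- chol2inv(chol(object$pooled_cov))
  scores <- vapply(object$classes, function(grp) {
    d <- sweep(x, 2, object$means[grp, ])
    -0.5 * rowSums((d %*% pinv) * d) + log(object$priors[[grp]])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(rownames(x), object$classes))
  if (type == "score") return(tibble::as_tibble(scores))
  object$classes[max.col(scores, ties.method = "first")]
}

#' Percent of correct classifications
#'
#' @param predicted,truth Label vectors of equal length.
#' @return `100 * mean(predicted == truth)`.
#' @export
classification_rate <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0) {
    abort("`predicted` and `truth` must be nonempty and equal length.")
  }
  100 * mean(as.character(predicted) == as.character(truth))
}

#' Per-class and total classification rates
#'
#' @param predicted,truth Label vectors of equal length.
#' @return Tibble with one row per class plus a `total` row: `class`, `n`,
#'   `correct`, `rate_pct`.
#' @export
classification_rates <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  per <- tibble::tibble(class = truth, ok = predicted == truth) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), correct = sum(.data$ok)) |>
    dplyr::ungroup()
  dplyr::bind_rows(
    per,
    tibble::tibble(class = "total", n = length(truth),
                   correct = sum(predicted == truth))
  ) |>
    dplyr::mutate(rate_pct = 100 * .data$correct / .data$n)
}
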