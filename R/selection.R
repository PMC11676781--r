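#' Build a stratified cross-validation fold plan
#'
#' Samples are partitioned into `k` folds ("cancelation groups"), shuffled
#' within class and dealt out cyclically so each fold's class proportions
#' match the overall ones to within one sample. Deterministic given the
#' seed.
#'
#' @param labels Class label per sample.
#' @param k Number of folds (default 7).
#' @param seed Integer seed.
#' @return Tibble `index`, `class`, `fold` with attributes `k` and `seed`.
#' @export
make_folds <- function(labels, k = 7, seed) {
  n <- length(labels)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort("`k` cannot exceed the number of samples.")
  if (missing(seed)) abort("`seed` is required.")
  labels <- as.character(labels)
  small <- names(which(table(labels) < k))
  if (length(small) > 0) {
    warn(paste0(
      "Class(es) with fewer than k members — stratification relaxed: ",
      paste(small, collapse = ", ")
    ))
  }
  fold <- integer(n)
  withr::with_seed(seed, {
    # deal folds cyclically within class, continuing the cycle across
    # classes so every fold is populated even when classes are small
    offset <- 0L
    for (grp in unique(labels)) {
      idx <- which(labels == grp)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  out <- tibble::tibble(index = seq_len(n), class = labels, fold = fold)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- seed
  out
}

#' Column-centred indicator coding of class labels
#'
#' One indicator column per class (rows sum to 1 before centring), then
#' each column centred to mean zero — the response block CovSel regresses
#' against when the response is a classification.
#'
#' @param labels Class label per sample, >= 2 classes.
#' @return Numeric matrix, n x G, columns named by class.
#' @export
dummy_code <- function(labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) abort("Need at least 2 classes to dummy-code.")
  y <- vapply(groups, function(grp) as.numeric(labels == grp),
              numeric(length(labels)))
  scale(y, center = TRUE, scale = FALSE)
}

#' CovSel: greedy covariance-based variable ordering
#'
#' At each step the variable whose (deflated) column has the largest sum of
#' squared covariances with the (deflated) response columns is selected;
#' then both the predictor block and the response block are deflated by
#' projection orthogonal to the selected column. Ties break to the lowest
#' column index; columns deflated to (numerically) zero norm are skipped.
#'
#' @param x Predictor matrix (autoscaled; columns are centred internally,
#'   which leaves covariances unchanged).
#' @param y Response matrix, e.g. [dummy_code()] output.
#' @param max_vars Number of variables to order (default all).
#' @return Integer vector of column indices in selection order, named by
#'   the column names of `x` when present.
#' @export
covsel_order <- function(x, y, max_vars = ncol(x)) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have matching rows.")
  if (max_vars < 1 || max_vars > ncol(x)) {
    abort("`max_vars` must be in 1..ncol(x).")
  }
  xd <- scale(x, center = TRUE, scale = FALSE)
  yd <- scale(y, center = TRUE, scale = FALSE)
  norm0 <- sqrt(colSums(xd^2))
  tol <- 1e-10 * max(norm0, 1)
  selected <- integer(0)
  for (step in seq_len(max_vars)) {
    norms <- sqrt(colSums(xd^2))
    live <- setdiff(which(norms > tol), selected)
    if (length(live) == 0) break
    score <- rowSums(crossprod(xd[, live, drop = FALSE], yd)^2)
    j <- live[which.max(score)] # which.max takes the first = lowest index
    selected <- c(selected, j)
    v <- xd[, j] / norms[j]
    xd <- xd - v %*% crossprod(v, xd)
    yd <- yd - v %*% crossprod(v, yd)
  }
  names(selected) <- colnames(x)[selected]
  selected
}

# Held-out misclassification counts for per-fold variable subsets.
# subsets: list (one per fold id in sort(unique(folds$fold))) of character
# vectors of element names. Returns total errors, or NA if any fold's LDA
# is infeasible (singular covariance / too few samples).
eval_subset_cv <- function(wide, folds, subsets) {
  fold_ids <- sort(unique(folds$fold))
  total <- 0L
  for (i in seq_along(fold_ids)) {
    f <- fold_ids[i]
    train <- wide[folds$fold != f, , drop = FALSE]
    test <- wide[folds$fold == f, , drop = FALSE]
    fit <- tryCatch(lda_fit(train, elements = subsets[[i]]),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_integer_)
    pred <- predict(fit, test)
    total <- total + sum(pred != test$class)
  }
  total
}

#' CovSel-LDA variable selection with cross-validated subset size
#'
#' Within each training fold the variables are ordered by [covsel_order()]
#' against the centred class indicators; for every subset size the LDA on
#' the ordered prefix is scored on the held-out fold. The retained size is
#' the smallest one achieving the minimum cross-validated
#' misclassification, and the final variables are the full-training-set
#' CovSel ordering truncated to that size.
#'
#' @param data Wide tibble (`class` + element columns), autoscaled
#'   training data.
#' @param k Folds (default 7).
#' @param max_vars Largest subset size examined; default
#'   `min(p, 10)`.
#' @param seed Integer seed for the fold plan.
#' @return An object of class `covsel_selection` (also
#'   `selection_result`): full-data `ordering`, `per_fold` orderings,
#'   `cv_curve` (size, errors, error_pct, feasible), `final_size`,
#'   `final_elements`, selection `frequencies`, `internal_cv_rate_pct`.
#' @export
covsel_select <- function(data, k = 7, max_vars = NULL, seed) {
  if (!is.data.frame(data) || !"class" %in% names(data)) {
    abort("`data` must be a wide table with a `class` column.")
  }
  if (missing(seed)) abort("`seed` is required.")
  elements <- setdiff(names(data), c("sample_id", "class"))
  p <- length(elements)
  if (is.null(max_vars)) max_vars <- min(p, 10L)
  if (max_vars < 1 || max_vars > p) abort("`max_vars` must be in 1..p.")
  folds <- make_folds(data$class, k = k, seed = seed)
  fold_ids <- sort(unique(folds$fold))

  x_all <- wide_matrix(data, elements)
  per_fold_order <- lapply(fold_ids, function(f) {
    tr <- folds$fold != f
    ord <- covsel_order(x_all[tr, , drop = FALSE],
                        dummy_code(data$class[tr]), max_vars = max_vars)
    elements[ord]
  })

  n <- nrow(data)
  cv_curve <- purrr::map_dfr(seq_len(max_vars), function(s) {
    subsets <- lapply(per_fold_order, function(ord) {
      ord[seq_len(min(s, length(ord)))]
    })
    errors <- eval_subset_cv(data, folds, subsets)
    tibble::tibble(size = s, errors = errors,
                   error_pct = 100 * errors / n,
                   feasible = !is.na(errors))
  })
  feasible <- cv_curve[cv_curve$feasible, ]
  if (nrow(feasible) == 0) abort("No feasible subset size for CovSel-LDA.")
  final_size <- feasible$size[which.min(feasible$errors)]

  full_order <- elements[covsel_order(x_all, dummy_code(data$class),
                                      max_vars = max_vars)]
  final_elements <- full_order[seq_len(final_size)]
  per_fold_sel <- lapply(per_fold_order, function(ord) {
    ord[seq_len(min(final_size, length(ord)))]
  })
  freqs <- aggregate_frequencies(per_fold_sel, levels = elements)

  structure(
    list(
      method = "covsel", elements = elements, ordering = full_order,
      per_fold = per_fold_sel, per_fold_order = per_fold_order,
      cv_curve = cv_curve, final_size = final_size,
      final_elements = final_elements, frequencies = freqs,
      internal_cv_rate_pct = 100 - min(feasible$error_pct),
      k = attr(folds, "k"), seed = seed, folds = folds
    ),
    class = c("covsel_selection", "selection_result")
  )
}

#' Forward stepwise Wilks'-lambda selection with cross-validation
#'
#' Within each cancelation group (training part of a fold): the variable
#' with the lowest univariate Wilks' lambda enters first (its one-way F
#' must pass `alpha`); thereafter the candidate giving the largest decrease
#' in the multivariate lambda enters if its partial F-to-enter p-value is
#' below `alpha` and the held-out misclassification does not increase.
#' The final model keeps the variables most frequently selected across the
#' groups, the count chosen by the best cross-validated classification;
#' frequency ties break to the lower mean univariate lambda, then to the
#' lower column index.
#'
#' @param data Wide tibble (`class` + element columns), autoscaled
#'   training data.
#' @param k Folds (default 7).
#' @param alpha Entry significance level for the partial F test (default
#'   0.05).
#' @param max_vars Cap on the per-group model size; default `min(p, 10)`.
#' @param seed Integer seed for the fold plan.
#' @return An object of class `stepwise_selection` (also
#'   `selection_result`): `per_fold` selections, ranked `frequencies`,
#'   `cv_curve` over top-m frequency sets, `final_elements`,
#'   `internal_cv_rate_pct`, per-variable `univariate` lambdas.
#' @export
stepwise_wilks <- function(data, k = 7, alpha = 0.05, max_vars = NULL,
                           seed) {
  if (!is.data.frame(data) || !"class" %in% names(data)) {
    abort("`data` must be a wide table with a `class` column.")
  }
  if (missing(seed)) abort("`seed` is required.")
  check_scalar_number(alpha, "alpha", positive = TRUE)
  elements <- setdiff(names(data), c("sample_id", "class"))
  p <- length(elements)
  if (is.null(max_vars)) max_vars <- min(p, 10L)
  labels <- as.character(data$class)
  g <- length(unique(labels))
  folds <- make_folds(labels, k = k, seed = seed)
  fold_ids <- sort(unique(folds$fold))
  x_all <- wide_matrix(data, elements)

  heldout_errors <- function(f, subset) {
    tr <- data[folds$fold != f, , drop = FALSE]
    te <- data[folds$fold == f, , drop = FALSE]
    fit <- tryCatch(lda_fit(tr, elements = subset),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_integer_)
    sum(predict(fit, te) != te$class)
  }

  per_fold_sel <- lapply(fold_ids, function(f) {
    tr <- folds$fold != f
    x_tr <- x_all[tr, , drop = FALSE]
    lab_tr <- labels[tr]
    n_tr <- sum(tr)

    uni <- vapply(elements, function(el) {
      wilks_univariate(x_tr[, el], lab_tr)$lambda
    }, numeric(1))
    first <- elements[which.min(uni)]
    entry <- partial_f_test(min(uni), 1, n_tr, g, 0)
    if (entry$p_value >= alpha) {
      abort("No variable passes the F-to-enter test at step 1.")
    }
    current <- first
    current_lambda <- min(uni)
    current_err <- heldout_errors(f, current)
    if (is.na(current_err)) current_err <- Inf

    while (length(current) < max_vars) {
      cands <- setdiff(elements, current)
      if (length(cands) == 0) break
      lam <- vapply(cands, function(el) {
        res <- tryCatch(
          wilks_multivariate(x_tr[, c(current, el), drop = FALSE], lab_tr),
          error = function(e) NULL
        )
        if (is.null(res)) NA_real_ else res$lambda
      }, numeric(1))
      if (all(is.na(lam))) break
      best <- cands[which.min(lam)]
      best_lambda <- min(lam, na.rm = TRUE)
      if (best_lambda > current_lambda) break
      ftest <- partial_f_test(best_lambda, current_lambda, n_tr, g,
                              length(current))
      if (ftest$p_value >= alpha) break
      new_err <- heldout_errors(f, c(current, best))
      if (is.na(new_err) || new_err > current_err) break
      current <- c(current, best)
      current_lambda <- best_lambda
      current_err <- new_err
    }
    current
  })

  uni_full <- vapply(elements, function(el) {
    wilks_univariate(x_all[, el], labels)$lambda
  }, numeric(1))
  freqs <- aggregate_frequencies(per_fold_sel, levels = elements,
                                 tie_values = uni_full)
  ranked <- freqs$variable
  n <- nrow(data)
  cv_curve <- purrr::map_dfr(seq_along(ranked), function(m) {
    subset <- ranked[seq_len(m)]
    errors <- eval_subset_cv(data, folds,
                             rep(list(subset), length(fold_ids)))
    tibble::tibble(size = m, errors = errors,
                   error_pct = 100 * errors / n,
                   feasible = !is.na(errors))
  })
  feasible <- cv_curve[cv_curve$feasible, ]
  if (nrow(feasible) == 0) abort("No feasible frequency-ranked subset.")
  final_size <- feasible$size[which.min(feasible$errors)]
  final_elements <- ranked[seq_len(final_size)]

  structure(
    list(
      method = "stepwise_wilks", elements = elements,
      per_fold = per_fold_sel, frequencies = freqs, cv_curve = cv_curve,
      final_size = final_size, final_elements = final_elements,
      internal_cv_rate_pct = 100 - min(feasible$error_pct),
      univariate = tibble::tibble(element = elements, lambda = uni_full),
      k = attr(folds, "k"), alpha = alpha, seed = seed, folds = folds
    ),
    class = c("stepwise_selection", "selection_result")
  )
}

#' Rank variables by selection frequency across cancelation groups
#'
#' @param selections List of per-fold selected variable sets (character
#'   vectors).
#' @param levels Candidate variables in column order, used for the final
#'   index tie-break; defaults to order of first appearance.
#' @param tie_values Optional named numeric (e.g. univariate lambdas);
#'   lower values rank first among equal counts.
#' @return Tibble `variable`, `count`, `rank`, most frequent first.
#' @export
#' @examples
#' aggregate_frequencies(list(c("A", "B"), "A", c("A", "C")))
aggregate_frequencies <- function(selections, levels = NULL,
                                  tie_values = NULL) {
  if (length(selections) == 0) abort("Need at least one fold selection.")
  all_vars <- unique(unlist(selections))
  if (is.null(levels)) levels <- all_vars
  counts <- vapply(all_vars, function(v) {
    sum(vapply(selections, function(s) v %in% s, logical(1)))
  }, integer(1))
  tie <- if (is.null(tie_values)) {
    rep(0, length(all_vars))
  } else {
    unname(tie_values[all_vars])
  }
  ord <- order(-counts, tie, match(all_vars, levels))
  tibble::tibble(
    variable = all_vars[ord],
    count = unname(counts[ord]),
    rank = seq_along(all_vars)
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection over %d folds\n",
              if (x$method == "covsel") "CovSel" else "Stepwise Wilks",
              x$k))
  cat("  retained:", paste(x$final_elements, collapse = ", "), "\n")
  cat(sprintf("  internal CV rate: %.1f%%\n", x$internal_cv_rate_pct))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$cv_curve

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, k = x$k, final_size = x$final_size,
    final_elements = paste(x$final_elements, collapse = ","),
    internal_cv_rate_pct = x$internal_cv_rate_pct
  )
}

#' Serialize a selection result to JSON
#'
#' @param x A `selection_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(
    list(
      method = x$method,
      final_elements = x$final_elements,
      per_fold = x$per_fold,
      frequencies = x$frequencies,
      cv_curve = x$cv_curve,
      internal_cv_rate_pct = x$internal_cv_rate_pct,
      k = x$k, seed = x$seed
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
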