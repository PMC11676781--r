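#' Stratified train/test split for external validation
#'
#' Draws a random test set of (about) `test_fraction` of the samples,
#' stratified by class: each class contributes `round-half-up(fraction *
#' class size)` test samples. With the default design (24/24/28 samples,
#' 45% test) that is 11/11/13 test and 41 training samples.
#'
#' @param labels Class label per sample.
#' @param test_fraction Fraction held out for external validation, in
#'   (0, 1). Default 0.45.
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`); otherwise a
#'   simple random draw of `round(fraction * n)` samples.
#' @return Tibble `index`, `class`, `set` (`"train"` / `"test"`), with the
#'   split parameters as attributes.
#' @export
split_train_test <- function(labels, test_fraction = 0.45, seed,
                             stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1.")
  }
  if (missing(seed)) abort("`seed` is required.")
  labels <- as.character(labels)
  n <- length(labels)
  if (stratified && any(table(labels) < 2)) {
    abort("Every class needs at least 2 members for a stratified split.")
  }
  test_idx <- withr::with_seed(seed, {
    if (stratified) {
      unlist(lapply(unique(labels), function(grp) {
        idx <- which(labels == grp)
        n_test <- floor(test_fraction * length(idx) + 0.5) # round half up
        idx[sample.int(length(idx), n_test)]
      }))
    } else {
      sample.int(n, floor(test_fraction * n + 0.5))
    }
  })
  out <- tibble::tibble(
    index = seq_len(n), class = labels,
    set = ifelse(seq_len(n) %in% test_idx, "test", "train")
  )
  attr(out, "test_fraction") <- test_fraction
  attr(out, "seed") <- seed
  attr(out, "stratified") <- stratified
  out
}

# Shared engine for the two end-to-end runs. The split comes first so
# that every fitted quantity — censoring retention, scaling, selection,
# model — is a function of the training rows only.
run_pipeline <- function(data, method, panel, test_fraction, k, alpha,
                         max_vars, priors, seed) {
  check_conc(data, flags = TRUE)
  wide_all <- conc_widen(data)
  split <- split_train_test(wide_all$class, test_fraction = test_fraction,
                            seed = seed)
  train_ids <- wide_all$sample_id[split$set == "train"]
  test_ids <- wide_all$sample_id[split$set == "test"]

  train_long <- filter_variables(data[data$sample_id %in% train_ids, ],
                                 panel)
  retained <- unique(train_long$element)
  test_long <- censor_substitute(
    data[data$sample_id %in% test_ids & data$element %in% retained, ],
    panel
  )

  scaling <- autoscale_fit(train_long)
  train_scaled <- conc_widen(autoscale_apply(train_long, scaling))
  test_scaled <- conc_widen(autoscale_apply(test_long, scaling))
  train_wide <- conc_widen(train_long)
  test_wide <- conc_widen(test_long)
  flags_kept <- dplyr::bind_rows(train_long, test_long)

  selection <- if (method == "covsel") {
    covsel_select(train_scaled, k = k, max_vars = max_vars,
                  seed = seed + 1L)
  } else {
    stepwise_wilks(train_scaled, k = k, alpha = alpha,
                   max_vars = max_vars, seed = seed + 1L)
  }

  model <- lda_fit(train_scaled, elements = selection$final_elements,
                   priors = priors)

  pred_train <- predict(model, train_scaled)
  pred_test <- predict(model, test_scaled)
  rates <- dplyr::bind_rows(
    dplyr::mutate(classification_rates(pred_train, train_scaled$class),
                  set = "train"),
    dplyr::mutate(classification_rates(pred_test, test_scaled$class),
                  set = "test")
  )
  external_rate <- rates$rate_pct[rates$set == "test" &
                                    rates$class == "total"]

  scores <- dplyr::bind_rows(
    dplyr::mutate(project_canonical(model, train_scaled), set = "train"),
    dplyr::mutate(project_canonical(model, test_scaled), set = "test")
  )

  structure(
    list(
      method = method,
      config = list(
        test_fraction = test_fraction, k = k, alpha = alpha,
        max_vars = max_vars, priors = priors, seed = seed,
        n_train = nrow(train_wide), n_test = nrow(test_wide),
        elements = retained
      ),
      split = split, scaling = scaling, selection = selection,
      model = model, rates = rates,
      internal_cv_rate_pct = selection$internal_cv_rate_pct,
      external_rate_pct = external_rate,
      scores = scores, data = flags_kept
    ),
    class = "flour_run"
  )
}

#' Run the CovSel-LDA classification pipeline end to end
#'
#' Censoring filter, stratified train/test split, autoscaling fitted on the
#' training set, CovSel variable ordering with k-fold cross-validated
#' subset-size choice, LDA fit, and internal (cross-validated) plus
#' external (held-out test set) classification rates, with
#' canonical-variate scores for plotting.
#'
#' @param data Long concentration table with censor flags.
#' @param panel Panel tibble (for the censoring policy).
#' @param test_fraction Held-out fraction for external validation
#'   (default 0.45).
#' @param k Cross-validation folds for the selection (default 7).
#' @param max_vars Largest subset size examined (default `min(p, 10)`).
#' @param priors LDA priors (see [lda_fit()]).
#' @param seed Integer seed driving the split (`seed`) and the fold plan
#'   (`seed + 1`).
#' @return A `flour_run` object; use `tidy()` for per-class rates,
#'   `glance()` for the one-row summary, `autoplot()` for the CV-space
#'   plot, [write_run_report()] to serialize.
#' @export
#' @examples
#' \donttest{
#' tbl <- simulate_flours(seed = 1)
#' run <- run_covsel_lda(tbl, seed = 1)
#' glance(run)
#' }
run_covsel_lda <- function(data, panel = insect_panel(),
                           test_fraction = 0.45, k = 7, max_vars = NULL,
                           priors = "equal", seed) {
  if (missing(seed)) abort("`seed` is required.")
  run_pipeline(data, "covsel", panel, test_fraction, k, alpha = NA,
               max_vars = max_vars, priors = priors, seed = seed)
}

#' Run the forward stepwise Wilks'-lambda LDA pipeline end to end
#'
#' As [run_covsel_lda()], with variable selection by forward stepwise
#' Wilks'-lambda inside each cancelation group, frequency aggregation
#' across groups, and the retained count chosen by cross-validated
#' classification.
#'
#' @inheritParams run_covsel_lda
#' @param alpha Entry significance level for the partial F test
#'   (default 0.05).
#' @return A `flour_run` object.
#' @export
run_stepwise_lda <- function(data, panel = insect_panel(),
                             test_fraction = 0.45, k = 7, alpha = 0.05,
                             max_vars = NULL, priors = "equal", seed) {
  if (missing(seed)) abort("`seed` is required.")
  run_pipeline(data, "stepwise", panel, test_fraction, k, alpha = alpha,
               max_vars = max_vars, priors = priors, seed = seed)
}

#' @export
print.flour_run <- function(x, ...) {
  cat(sprintf(
    "%s-LDA run: %d train / %d test samples\n",
    if (x$method == "covsel") "CovSel" else "Stepwise-Wilks",
    x$config$n_train, x$config$n_test
  ))
  cat("  selected:", paste(x$selection$final_elements, collapse = ", "),
      "\n")
  cat(sprintf("  internal CV rate: %.1f%%   external rate: %.1f%%\n",
              x$internal_cv_rate_pct, x$external_rate_pct))
  invisible(x)
}

#' @export
tidy.flour_run <- function(x, ...) x$rates

#' @export
glance.flour_run <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_train = x$config$n_train, n_test = x$config$n_test,
    selected = paste(x$selection$final_elements, collapse = ","),
    internal_cv_rate_pct = x$internal_cv_rate_pct,
    external_rate_pct = x$external_rate_pct
  )
}

#' @export
#' @rdname run_covsel_lda
#' @param object A `flour_run` (for `autoplot`).
#' @param ... Unused.
autoplot.flour_run <- function(object, ...) {
  sc <- object$scores
  if (!"CV2" %in% names(sc)) sc$CV2 <- 0
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$CV1, y = .data$CV2,
                                   colour = .data$class,
                                   shape = .data$set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(train = 16, test = 1)) +
    ggplot2::labs(
      x = "CV1", y = "CV2",
      title = sprintf("Canonical-variate space (%s-LDA)", object$method),
      colour = "class", shape = "set"
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a pipeline run to JSON and CSV artifacts
#'
#' Writes `report.json` (config, selection, rates), `cv_scores.csv`
#' (canonical-variate coordinates for train and test samples) and
#' `selection.csv` (cross-validated error per subset size) under `dir`.
#'
#' @param run A `flour_run`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_run_report <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    report = file.path(dir, "report.json"),
    scores = file.path(dir, "cv_scores.csv"),
    selection = file.path(dir, "selection.csv")
  )
  jsonlite::write_json(
    list(
      method = run$method,
      config = run$config,
      selected_elements = run$selection$final_elements,
      selection_frequencies = run$selection$frequencies,
      rates = run$rates,
      internal_cv_rate_pct = run$internal_cv_rate_pct,
      external_rate_pct = run$external_rate_pct
    ),
    paths[["report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_csv(run$scores, paths[["scores"]])
  readr::write_csv(run$selection$cv_curve, paths[["selection"]])
  invisible(paths)
}
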