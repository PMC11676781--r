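#' Apply the censored-variable policy before modelling
#'
#' Elements whose cells are below the LOD throughout the table carry no
#' quantitative information and are dropped (in the default panel this
#' removes boron). Cells between LOD and LOQ keep their measured value —
#' they are imprecise, not absent, and can still discriminate. Isolated
#' below-LOD cells of otherwise quantified elements are substituted by
#' LOD/2 (`policy = "substitute"`) or kept as measured
#' (`policy = "keep"`).
#'
#' Idempotent: filtering a filtered table changes nothing.
#'
#' @param data Long concentration table with `flag`s (see
#'   [apply_censoring()]).
#' @param panel Panel tibble supplying each element's LOD (needed only for
#'   substitution).
#' @param policy `"substitute"` (default) or `"keep"`.
#' @return The filtered long table; warns when nothing survives.
#' @export
filter_variables <- function(data, panel = insect_panel(),
                             policy = c("substitute", "keep")) {
  check_conc(data, flags = TRUE)
  policy <- match.arg(policy)
  dropped <- data |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(all_lod = all(.data$flag == "below_lod")) |>
    dplyr::filter(.data$all_lod) |>
    dplyr::pull(.data$element)
  out <- dplyr::filter(data, !(.data$element %in% dropped))
  if (nrow(out) == 0) warn("No elements survive the censoring filter.")
  if (policy == "substitute") out <- censor_substitute(out, panel)
  out
}

#' Substitute LOD/2 for below-LOD cells without dropping elements
#'
#' The substitution half of the censoring policy, applied on its own when
#' the element set has already been fixed (e.g. on a test set, using the
#' training set's retention decision).
#'
#' @param data Long concentration table with `flag`s.
#' @param panel Panel tibble supplying each element's LOD.
#' @return `data` with below-LOD values replaced by LOD/2.
#' @export
censor_substitute <- function(data, panel = insect_panel()) {
  check_conc(data, flags = TRUE)
  if (!any(data$flag == "below_lod")) return(data)
  limits <- dplyr::distinct(panel[, c("element", "lod")],
                            .data$element, .keep_all = TRUE)
  out <- dplyr::left_join(data, limits, by = "element")
  out <- dplyr::mutate(
    out,
    value = dplyr::if_else(.data$flag == "below_lod",
                           .data$lod / 2, .data$value)
  )
  dplyr::select(out, -"lod")
}

#' Fit autoscaling parameters
#'
#' Autoscaling (z-scoring) is the standard chemometric preprocessing: each
#' element is centred on its mean and divided by its standard deviation
#' (n - 1 denominator) so that concentration scale differences spanning
#' orders of magnitude (P at thousands of ug/g, Cd at hundredths) do not
#' dominate the multivariate analysis. Parameters are fitted on training
#' data only and applied unchanged to test data.
#'
#' @param data Long concentration table (training samples).
#' @return A tibble `element, mean, sd` of class `scaling_params`.
#' @export
autoscale_fit <- function(data) {
  check_conc(data)
  n <- length(unique(data$sample_id))
  if (n < 2) abort("Autoscaling needs at least 2 samples.")
  params <- data |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value)) |>
    dplyr::ungroup()
  flat <- params$element[params$sd == 0]
  if (length(flat) > 0) {
    abort(paste0("Constant element column(s), sd = 0: ",
                 paste(flat, collapse = ", ")))
  }
  class(params) <- c("scaling_params", class(params))
  params
}

#' Apply autoscaling parameters
#'
#' @param data Long concentration table (training or test samples).
#' @param params Output of [autoscale_fit()]. Every element in `data` must
#'   be covered.
#' @return `data` with `value` replaced by `(value - mean) / sd`.
#' @export
autoscale_apply <- function(data, params) {
  check_conc(data)
  missing <- setdiff(unique(data$element), params$element)
  if (length(missing) > 0) {
    abort(paste0("No scaling parameters for element(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- dplyr::left_join(
    data, dplyr::select(params, "element", .mean = "mean", .sd = "sd"),
    by = "element"
  )
  out <- dplyr::mutate(out, value = (.data$value - .data$.mean) / .data$.sd)
  dplyr::select(out, -".mean", -".sd")
}

#' Principal component analysis of an autoscaled concentration table
#'
#' PCA on the sample covariance of the (autoscaled) data: loadings are its
#' eigenvectors ordered by eigenvalue, scores are the projections of the
#' samples, and each component's explained variance is its eigenvalue as a
#' percentage of the total. Computed via [stats::prcomp()]. Eigenvector
#' sign is arbitrary, so each loading is flipped to make its
#' largest-magnitude entry positive — this pins down plots and snapshot
#' comparisons.
#'
#' @param data Long concentration table, already autoscaled (the function
#'   does not rescale; it does centre).
#' @param n_components Number of components to keep; defaults to
#'   `min(n_samples - 1, n_elements)`.
#' @return An object of class `elemental_pca`: `loadings` (elements x
#'   components), `scores` tibble, `explained_variance` (percent per kept
#'   component), `elements`. `tidy()`, `glance()` and `autoplot()` methods
#'   are provided.
#' @export
#' @examples
#' tbl <- simulate_flours(seed = 1)
#' scaled <- autoscale_apply(tbl, autoscale_fit(tbl))
#' pca <- elemental_pca(scaled)
#' glance(pca)
elemental_pca <- function(data, n_components = NULL) {
  check_conc(data)
  wide <- conc_widen(data)
  x <- wide_matrix(wide)
  max_k <- min(nrow(x) - 1L, ncol(x))
  k <- if (is.null(n_components)) max_k else as.integer(n_components)
  if (k < 1 || k > max_k) {
    abort(paste0("`n_components` must be between 1 and ", max_k, "."))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  expl <- 100 * ev / sum(ev)

  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|entry| of each loading made positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))

  structure(
    list(
      loadings = loadings,
      scores = dplyr::bind_cols(wide[, c("sample_id", "class")],
                                tibble::as_tibble(scores)),
      explained_variance = expl[seq_len(k)],
      center = pc$center,
      elements = colnames(x),
      n = nrow(x)
    ),
    class = "elemental_pca"
  )
}

#' @export
print.elemental_pca <- function(x, ...) {
  k <- length(x$explained_variance)
  cat(sprintf("PCA of %d samples x %d elements, %d component(s)\n",
              x$n, length(x$elements), k))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname elemental_pca
#' @param x An `elemental_pca` object.
#' @param matrix For `tidy()`: `"scores"` (default), `"loadings"` or
#'   `"eigenvalues"`.
#' @param ... Unused.
tidy.elemental_pca <- function(x, matrix = c("scores", "loadings",
                                             "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                                 names_to = "component",
                                 values_to = "score"),
    loadings = tibble::as_tibble(x$loadings, rownames = "element") |>
      tidyr::pivot_longer(dplyr::starts_with("PC"),
                          names_to = "component", values_to = "loading"),
    eigenvalues = tibble::tibble(
      component = paste0("PC", seq_along(x$explained_variance)),
      explained_variance_pct = x$explained_variance,
      cumulative_pct = cumsum(x$explained_variance)
    )
  )
}

#' @export
glance.elemental_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n, n_elements = length(x$elements),
    n_components = length(x$explained_variance),
    var_pc1 = x$explained_variance[1],
    var_pc2 = if (length(x$explained_variance) > 1) {
      x$explained_variance[2]
    } else {
      NA_real_
    }
  )
}

#' Biplot coordinates for a fitted PCA
#'
#' Sample scores plus one loading ray per element on a pair of principal
#' components — the joint sample/variable view used to read which elements
#' drive which class separations. Rays are the raw orthonormal loadings
#' (length <= 1); `scale_rays` stretches them for display against the
#' score cloud.
#'
#' @param model An `elemental_pca` object.
#' @param components Integer pair, default `c(1, 2)`.
#' @param scale_rays Multiplier applied to rays for display. Default 1.
#' @return List with `scores` (tibble: sample_id, class, x, y) and `rays`
#'   (tibble: element, x, y).
#' @export
biplot_coords <- function(model, components = c(1, 2), scale_rays = 1) {
  if (!inherits(model, "elemental_pca")) {
    abort("`model` must be an `elemental_pca` object.")
  }
  k <- length(model$explained_variance)
  if (length(components) != 2 || any(components < 1) ||
      any(components > k)) {
    abort(paste0("`components` must be two indices in 1..", k, "."))
  }
  pcs <- paste0("PC", components)
  list(
    scores = tibble::tibble(
      sample_id = model$scores$sample_id,
      class = model$scores$class,
      x = model$scores[[pcs[1]]],
      y = model$scores[[pcs[2]]]
    ),
    rays = tibble::tibble(
      element = rownames(model$loadings),
      x = scale_rays * model$loadings[, pcs[1]],
      y = scale_rays * model$loadings[, pcs[2]]
    )
  )
}

#' @export
#' @rdname elemental_pca
#' @param object An `elemental_pca` object (for `autoplot`).
#' @param components Which pair of components to draw.
#' @param scale_rays Ray stretch factor for readability.
autoplot.elemental_pca <- function(object, components = c(1, 2),
                                   scale_rays = NULL, ...) {
  bp <- biplot_coords(object, components)
  if (is.null(scale_rays)) {
    scale_rays <- 0.8 * max(abs(c(bp$scores$x, bp$scores$y)))
  }
  ev <- object$explained_variance[components]
  ggplot2::ggplot(bp$scores, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class,
                                     shape = .data$class), size = 2) +
    ggplot2::geom_segment(
      data = bp$rays,
      ggplot2::aes(x = 0, y = 0, xend = scale_rays * .data$x,
                   yend = scale_rays * .data$y),
      inherit.aes = FALSE, colour = "grey40",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = bp$rays,
      ggplot2::aes(x = 1.07 * scale_rays * .data$x,
                   y = 1.07 * scale_rays * .data$y,
                   label = .data$element),
      inherit.aes = FALSE, size = 3, colour = "grey20"
    ) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1], ev[1]),
      y = sprintf("PC%d (%.1f%%)", components[2], ev[2]),
      colour = "class", shape = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Pearson correlation between two element profiles
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Pearson product-moment correlation in [-1, 1].
#' @export
#' @examples
#' element_correlation(1:4, c(2, 4, 6, 8)) # 1
element_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for zero-variance input.")
  }
  cor(x, y)
}
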