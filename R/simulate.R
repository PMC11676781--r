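#' Simulate a multi-element concentration table
#'
#' Draws per-sample elemental concentrations for each flour class from
#' independent normal distributions with mean equal to the panel's class
#' mean and standard deviation `cv * mean`, truncated at zero (negative
#' draws are redrawn; with `cv <= 0.2` this is vanishingly rare). The
#' generator emulates the between-aliquot variability of a real ICP-MS
#' study so the downstream chemometrics can be exercised end to end.
#'
#' @param panel Panel tibble (element x class means and limits), see
#'   [insect_panel()].
#' @param n_per_class Named integer vector of samples per class; defaults
#'   to the study design of 24 cricket, 24 buffalo worm and 28 mealworm
#'   samples.
#' @param cv Within-class coefficient of variation (sd/mean), shared across
#'   elements. Default 0.10.
#' @param seed Integer seed; the same panel and seed give a bit-identical
#'   table. Required.
#' @param censor If `TRUE` (default) censor flags are attached by
#'   [apply_censoring()]; otherwise every cell is flagged `"observed"`.
#' @return A long concentration table: `sample_id`, `class`, `element`,
#'   `value` (ug/g dry), `flag`.
#' @export
#' @examples
#' tbl <- simulate_flours(seed = 1)
#' dplyr::count(tbl, class) # 24/24/28 samples per class
simulate_flours <- function(panel = insect_panel(),
                            n_per_class = default_class_sizes(),
                            cv = 0.1, seed, censor = TRUE) {
  check_panel(panel)
  check_scalar_number(cv, "cv", nonneg = TRUE)
  if (missing(seed)) abort("`seed` is required; seeds are always explicit.")
  classes <- unique(panel$class)
  bad <- setdiff(names(n_per_class), classes)
  if (length(bad) > 0) {
    abort(paste0("Unknown class label(s) in `n_per_class`: ",
                 paste(bad, collapse = ", ")))
  }
  if (!all(classes %in% names(n_per_class)) || any(n_per_class < 1)) {
    abort("`n_per_class` must give a count >= 1 for every panel class.")
  }
  elements <- unique(panel$element)

  tbl <- withr::with_seed(seed, {
    purrr::map_dfr(classes, function(cl) {
      n <- as.integer(n_per_class[[cl]])
      ids <- sprintf("%s_%02d", cl, seq_len(n))
      purrr::map_dfr(elements, function(el) {
        mu <- panel$mean[panel$element == el & panel$class == cl]
        vals <- rnorm_trunc0(n, mean = mu, sd = cv * mu)
        tibble::tibble(sample_id = ids, class = cl, element = el,
                       value = vals)
      })
    })
  })
  tbl <- dplyr::arrange(
    tbl,
    match(.data$class, classes), .data$sample_id, match(.data$element, elements)
  )
  if (censor) {
    apply_censoring(tbl, panel)
  } else {
    dplyr::mutate(tbl, flag = "observed")
  }
}

# zero-truncated normal draws; redraws the (rare) negative values so the
# stream stays deterministic under a fixed seed
rnorm_trunc0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(x < 0)) {
    neg <- x < 0
    x[neg] <- rnorm(sum(neg), mean, sd)
  }
  x
}

#' Flag concentrations against detection and quantification limits
#'
#' Compares each cell to its element's LOD and LOQ and records the censor
#' status: `below_lod` (< LOD), `below_loq` (in [LOD, LOQ)) or `observed`
#' (>= LOQ). Numeric values are kept unchanged — censoring is a flag, not a
#' substitution (substitution policy lives in [filter_variables()]).
#'
#' @param data Long concentration table.
#' @param panel Panel tibble providing `lod`/`loq` for every element in
#'   `data`.
#' @return `data` with a (re)computed `flag` column.
#' @export
apply_censoring <- function(data, panel = insect_panel()) {
  check_conc(data)
  limits <- dplyr::distinct(
    panel[, c("element", "lod", "loq")], .data$element, .keep_all = TRUE
  )
  missing <- setdiff(unique(data$element), limits$element)
  if (length(missing) > 0) {
    abort(paste0("No panel limits for element(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- dplyr::left_join(
    dplyr::select(data, -dplyr::any_of("flag")), limits, by = "element"
  )
  out <- dplyr::mutate(
    out,
    flag = dplyr::case_when(
      .data$value < .data$lod ~ "below_lod",
      .data$value < .data$loq ~ "below_loq",
      TRUE ~ "observed"
    )
  )
  dplyr::select(out, -"lod", -"loq")
}

#' Simulate instrument responses of blank samples
#'
#' Blank replicates carry the baseline noise from which the blank standard
#' deviation — the numerator of the LOD/LOQ formulas — is estimated.
#'
#' @param sd_blank Standard deviation of the blank response (>= 0).
#' @param n Number of independent blanks (>= 2); the method uses 6.
#' @param seed Integer seed.
#' @return Numeric vector of `n` zero-mean responses.
#' @export
simulate_blanks <- function(sd_blank, n = 6, seed) {
  check_scalar_number(sd_blank, "sd_blank", nonneg = TRUE)
  if (!is.numeric(n) || n < 2) abort("`n` must be at least 2 blanks.")
  if (missing(seed)) abort("`seed` is required.")
  withr::with_seed(seed, rnorm(as.integer(n), mean = 0, sd = sd_blank))
}

#' Simulate a calibration-standard series
#'
#' Generates instrument responses for working standards of known,
#' increasing concentration: `response = intercept + slope * level + noise`.
#'
#' @param slope,intercept True line parameters (response per ug/L, response
#'   units).
#' @param levels Standard concentrations in ug/L; at least 3 distinct,
#'   strictly positive values.
#' @param noise_sd Standard deviation of the additive response noise.
#' @param seed Integer seed.
#' @return Tibble with `level` (ug/L) and `response`.
#' @export
#' @examples
#' simulate_calibration(2, 0, levels = c(0.5, 5, 50, 400),
#'                      noise_sd = 0.01, seed = 1)
simulate_calibration <- function(slope, intercept, levels, noise_sd, seed) {
  check_scalar_number(slope, "slope")
  check_scalar_number(intercept, "intercept")
  check_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(unique(levels)) < 3) {
    abort("`levels` must contain at least 3 distinct standards.")
  }
  if (any(levels <= 0)) abort("Standard levels must be strictly positive.")
  if (missing(seed)) abort("`seed` is required.")
  response <- withr::with_seed(
    seed, intercept + slope * levels + rnorm(length(levels), 0, noise_sd)
  )
  tibble::tibble(level = as.numeric(levels), response = response)
}
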