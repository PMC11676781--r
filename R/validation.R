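#' Fit a straight-line calibration curve
#'
#' Ordinary least-squares fit of instrument response against standard
#' concentration. The coefficient of determination is the squared Pearson
#' correlation between response and fit, which for a straight line equals
#' the usual regression R-squared.
#'
#' @param data Data frame with the standard series.
#' @param level,response Column names (strings) holding the standard
#'   concentrations (ug/L) and instrument responses.
#' @param element Optional element label carried into the result.
#' @return An object of class `calibration_fit` with `slope`, `intercept`,
#'   `r_squared`, `lloq`/`hloq` (the working-range bounds, min and max
#'   standard level) and the data used. `tidy()` and `glance()` methods are
#'   provided.
#' @export
#' @examples
#' std <- simulate_calibration(2, 0, c(0.5, 5, 50, 400), 0.01, seed = 1)
#' glance(fit_calibration(std))
fit_calibration <- function(data, level = "level", response = "response",
                            element = NA_character_) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!all(c(level, response) %in% names(data))) {
    abort("`data` must contain the `level` and `response` columns.")
  }
  x <- data[[level]]
  y <- data[[response]]
  if (length(x) < 3) abort("A calibration needs at least 3 points.")
  if (length(unique(x)) < 2) {
    abort("All standard levels are identical; the slope is undefined.")
  }
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  r2 <- if (var(yhat) == 0) 0 else cor(y, yhat)^2
  structure(
    list(
      element = element,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      lloq = min(x),
      hloq = max(x),
      n = length(x),
      data = tibble::tibble(level = x, response = y)
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration fit", if (!is.na(x$element)) paste0("(", x$element, ")"),
      "\n", sep = " ")
  cat(sprintf("  response = %.6g + %.6g * level (ug/L)\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.4f over working range %g-%g ug/L (%d standards)\n",
              x$r_squared, x$lloq, x$hloq, x$n))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    element = x$element, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, lloq = x$lloq, hloq = x$hloq, n = x$n
  )
}

#' Limits of detection and quantification from blank noise
#'
#' `LOD = 3 * sd_blank / slope` and `LOQ = 10 * sd_blank / slope`, with the
#' blank standard deviation measured in response units and the calibration
#' slope converting to concentration units. The LOQ/LOD ratio is exactly
#' 10/3 by construction.
#'
#' @param sd_blank Standard deviation of replicate blank responses (>= 0).
#' @param slope Calibration slope (> 0), response per ug/L.
#' @return Tibble with `lod` and `loq` in solution units (ug/L).
#' @export
#' @examples
#' lod_loq(sd_blank = 1, slope = 2) # lod 1.5, loq 5
lod_loq <- function(sd_blank, slope) {
  check_scalar_number(sd_blank, "sd_blank", nonneg = TRUE)
  check_scalar_number(slope, "slope")
  if (slope <= 0) abort("`slope` must be > 0 to convert blank noise.")
  tibble::tibble(lod = 3 * sd_blank / slope, loq = 10 * sd_blank / slope)
}

#' Convert a solution concentration to dry-mass units
#'
#' The digestion brings `sample_mass_g` of dried flour to
#' `final_volume_l` of solution, so a solution concentration in ug/L maps
#' to `conc * volume / mass` ug/g of dry sample. The method's defaults are
#' 50 mg brought to 100 mL.
#'
#' @param conc Concentration in ug/L (vectorised).
#' @param final_volume_l Final solution volume in litres (> 0).
#' @param sample_mass_g Dry sample mass in grams (> 0).
#' @return Concentration(s) in ug/g dry mass.
#' @export
#' @examples
#' solution_to_dry(1, 0.1, 0.05) # 2 ug/g
solution_to_dry <- function(conc, final_volume_l = 0.1,
                            sample_mass_g = 0.05) {
  check_scalar_number(final_volume_l, "final_volume_l", positive = TRUE)
  check_scalar_number(sample_mass_g, "sample_mass_g", positive = TRUE)
  conc * final_volume_l / sample_mass_g
}

#' Spike recovery
#'
#' `100 * (C_spiked - C_native) / C_added`: the percentage of a known added
#' analyte amount returned by the full analytical procedure.
#'
#' @param c_spiked Concentration measured after addition.
#' @param c_native Concentration before addition.
#' @param c_added Concentration added (> 0).
#' @return Recovery in percent (vectorised).
#' @export
#' @examples
#' recovery_pct(15, 5, 10) # 100
#' recovery_pct(14, 5, 10) # 90
recovery_pct <- function(c_spiked, c_native, c_added) {
  if (any(c_added <= 0)) abort("`c_added` must be > 0.")
  100 * (c_spiked - c_native) / c_added
}

#' Relative standard deviation of replicate measurements
#'
#' `100 * sd / mean` with the sample standard deviation (n - 1 denominator),
#' the method's precision figure of merit, estimated from replicates of
#' unfortified samples.
#'
#' @param x Numeric vector of at least 2 replicates with nonzero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd_pct(c(8, 10, 12)) # 20
rsd_pct <- function(x) {
  if (length(x) < 2) abort("RSD needs at least 2 replicates.")
  m <- mean(x)
  if (m == 0) abort("RSD is undefined for replicates with mean 0.")
  100 * sd(x) / m
}

#' Assemble a per-element method-validation report
#'
#' Combines calibration standards, blank replicates and spiked/unspiked
#' replicate measurements into the per-element figures of merit of a
#' Eurachem-style validation: calibration slope and R-squared, working
#' range, RSD, recovery per matrix, and LOD/LOQ converted to dry-mass
#' units. Recoveries outside the acceptance band are flagged.
#'
#' @param standards Data frame `element, level, response` (level in ug/L).
#' @param blanks Data frame `element, response` with >= 2 blanks per
#'   element.
#' @param replicates Data frame `element, matrix, spiked, value` (and, for
#'   spiked rows, `added`), values in ug/g dry. `spiked` is logical. RSD is
#'   computed from the unspiked replicates (per matrix, then averaged);
#'   recovery per matrix from the spiked/unspiked means and the added
#'   amount.
#' @param final_volume_l,sample_mass_g Digestion volume and dry mass used
#'   to convert LOD/LOQ to ug/g dry; defaults 100 mL and 50 mg.
#' @param recovery_band Acceptance band for recovery, percent. Default
#'   `c(90, 110)`.
#' @return A tibble, one row per element: calibration figures, `rsd_pct`,
#'   one `recovery_<matrix>` column per matrix, `lod_dry`, `loq_dry`
#'   (ug/g), and `recovery_ok` (FALSE when any matrix recovery falls
#'   outside the band).
#' @export
validation_report <- function(standards, blanks, replicates,
                              final_volume_l = 0.1, sample_mass_g = 0.05,
                              recovery_band = c(90, 110)) {
  for (nm in c("standards", "blanks", "replicates")) {
    if (!is.data.frame(get(nm))) abort(paste0("`", nm, "` must be a data frame."))
  }
  if (!all(c("element", "level", "response") %in% names(standards))) {
    abort("`standards` needs columns element, level, response.")
  }
  if (!all(c("element", "response") %in% names(blanks))) {
    abort("`blanks` needs columns element, response.")
  }
  if (!all(c("element", "matrix", "spiked", "value") %in% names(replicates))) {
    abort("`replicates` needs columns element, matrix, spiked, value.")
  }
  elements <- unique(standards$element)
  for (nm in c("blanks", "replicates")) {
    other <- unique(get(nm)$element)
    if (!setequal(other, elements)) {
      abort(paste0(
        "Element sets differ between `standards` and `", nm, "`: ",
        paste(union(setdiff(elements, other), setdiff(other, elements)),
              collapse = ", ")
      ))
    }
  }

  purrr::map_dfr(elements, function(el) {
    cal <- fit_calibration(standards[standards$element == el, ],
                           element = el)
    sd_blank <- sd(blanks$response[blanks$element == el])
    limits <- lod_loq(sd_blank, cal$slope)
    rep_el <- replicates[replicates$element == el, ]
    matrices <- unique(rep_el$matrix)

    per_matrix <- purrr::map_dfr(matrices, function(mx) {
      sub <- rep_el[rep_el$matrix == mx, ]
      unspiked <- sub$value[!sub$spiked]
      spiked <- sub$value[sub$spiked]
      added <- unique(sub$added[sub$spiked])
      if (length(added) != 1 || !is.finite(added)) {
        abort(paste0("Spiked replicates for ", el, "/", mx,
                     " need a single `added` amount."))
      }
      tibble::tibble(
        matrix = mx,
        rsd = rsd_pct(unspiked),
        recovery = recovery_pct(mean(spiked), mean(unspiked), added)
      )
    })

    out <- tibble::tibble(
      element = el,
      slope = cal$slope,
      intercept = cal$intercept,
      r_squared = cal$r_squared,
      lloq = cal$lloq,
      hloq = cal$hloq,
      rsd_pct = mean(per_matrix$rsd),
      lod_dry = solution_to_dry(limits$lod, final_volume_l, sample_mass_g),
      loq_dry = solution_to_dry(limits$loq, final_volume_l, sample_mass_g),
      recovery_ok = all(per_matrix$recovery >= recovery_band[1] &
                          per_matrix$recovery <= recovery_band[2])
    )
    rec <- setNames(as.list(per_matrix$recovery),
                    paste0("recovery_", per_matrix$matrix))
    dplyr::bind_cols(out, tibble::as_tibble(rec))
  })
}

#' Write a validation report to CSV and JSON
#'
#' @param report Tibble from [validation_report()].
#' @param csv_path,json_path Output files; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_validation_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report, csv_path)
  if (!is.null(json_path)) {
    keyed <- setNames(
      lapply(seq_len(nrow(report)), function(i) as.list(report[i, -1])),
      report$element
    )
    jsonlite::write_json(keyed, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
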