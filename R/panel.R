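#' Default multi-element panel for insect flours
#'
#' Per-class mean concentrations (ug/g dry mass) together with the method's
#' limit of detection (LOD) and limit of quantification (LOQ) for the 20
#' isotopes quantified by the ICP-MS method, for the three flour classes:
#' cricket (*Acheta domesticus*), buffalo worm (*Alphitobius diaperinus*)
#' and mealworm (*Tenebrio molitor*).
#'
#' Cells that the method cannot quantify get imputed means flagged in
#' `censor`: boron sits below the LOD in every class (mean placed at LOD/2);
#' Se and Sr in buffalo worms and Cr in mealworms fall between LOD and LOQ
#' (mean placed at (LOD+LOQ)/2). Two iron isotopes are carried because the
#' method monitors both.
#'
#' @return A tibble with one row per element x class: `element` (isotope
#'   label), `class`, `mean` (ug/g dry), `lod`, `loq` (ug/g dry) and
#'   `censor` (`"observed"`, `"below_loq"` or `"below_lod"` describing how
#'   the class mean was obtained).
#' @export
#' @examples
#' insect_panel()
insect_panel <- function() {
  # element, cricket, buffalo_worm, mealworm, lod, loq (all ug/g dry)
  rows <- tibble::tribble(
    ~element, ~cricket, ~buffalo_worm, ~mealworm, ~lod, ~loq,
    "10B",        NA,       NA,       NA,   5,      17,
    "23Na",     2900,     1760,      560,   3,       9,
    "24Mg",      464,      550,     1160,   4.5,    15,
    "27Al",      260,      220,       80,   0.8,     3,
    "31P",      8400,     7200,     6800,   0.2,     0.7,
    "39K",     10000,    11400,     9800,  23,      73,
    "44Ca",     1220,      680,      380, 120,     393,
    "52Cr",        0.2,      0.4,     NA,   0.02,    0.07,
    "55Mn",       46.6,      6.6,     13.4,  0.3,    1,
    "56Fe",       60,       52,       56,   0.0002,  0.0007,
    "57Fe",       80,       68,       78,   0.004,   0.013,
    "59Co",        0.04,     0.06,     0.06, 0.004,  0.013,
    "60Ni",        0.6,      0.6,      0.6,  0.15,   0.5,
    "64Zn",      320,      130,      140,   3,       9,
    "65Cu",       38,       38,       22,   0.07,    0.2,
    "80Se",        0.54,    NA,        0.28, 0.07,   0.25,
    "88Sr",        4.2,     NA,        3.24, 0.5,    2,
    "98Mo",        0.8,      0.78,     1.42, 0.04,   0.13,
    "111Cd",       0.032,    0.032,    0.048, 0.01,  0.03,
    "138Ba",       2.88,     0.52,     3.3,  0.04,   0.12
  )
  long <- tidyr::pivot_longer(
    rows,
    cols = c("cricket", "buffalo_worm", "mealworm"),
    names_to = "class", values_to = "mean"
  )
  long <- dplyr::mutate(
    long,
    censor = dplyr::case_when(
      !is.na(.data$mean) ~ "observed",
      .data$element == "10B" ~ "below_lod",
      TRUE ~ "below_loq"
    ),
    # imputed means for unquantifiable cells: LOD/2 below the LOD,
    # midway between the limits for between-LOD-and-LOQ cells
    mean = dplyr::case_when(
      .data$censor == "below_lod" ~ .data$lod / 2,
      .data$censor == "below_loq" ~ (.data$lod + .data$loq) / 2,
      TRUE ~ .data$mean
    )
  )
  dplyr::select(long, "element", "class", "mean", "lod", "loq", "censor")
}

#' Class labels of the default insect-flour panel
#' @return Character vector of the three flour classes in canonical order.
#' @export
insect_classes <- function() c("cricket", "buffalo_worm", "mealworm")

#' Default per-class sample counts of the study design
#' @return Named integer vector: 24 cricket, 24 buffalo worm, 28 mealworm.
#' @export
default_class_sizes <- function() {
  c(cricket = 24L, buffalo_worm = 24L, mealworm = 28L)
}

#' Calibration working ranges of the ICP-MS method
#'
#' Lowest and highest calibration-standard concentrations (ug/L) bracketing
#' the working range of each isotope's calibration line.
#'
#' @return Tibble with `element`, `lloq_ugL`, `hloq_ugL`.
#' @export
calibration_ranges <- function() {
  tibble::tribble(
    ~element, ~lloq_ugL, ~hloq_ugL,
    "10B",      0.5,    400,
    "23Na",   150,     3000,
    "24Mg",    75,     3000,
    "27Al",     0.2,    160,
    "31P",    300,     8000,
    "39K",    300,     8000,
    "44Ca",    50,     1000,
    "52Cr",     0.1,     80,
    "55Mn",     0.2,     40,
    "57Fe",     2,      400,
    "59Co",     0.05,    40,
    "60Ni",     0.1,     80,
    "64Zn",     0.5,    400,
    "65Cu",     0.1,     80,
    "80Se",     0.5,    400,
    "88Sr",     0.25,    20,
    "98Mo",     0.25,    20,
    "111Cd",    0.05,    40,
    "138Ba",    0.2,    160
  )
}

check_panel <- function(panel) {
  if (!is.data.frame(panel)) abort("`panel` must be a data frame.")
  need <- c("element", "class", "mean", "lod", "loq")
  missing <- setdiff(need, names(panel))
  if (length(missing) > 0) {
    abort(paste0("`panel` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(panel$mean)) || any(panel$mean < 0)) {
    abort("Panel class means must be finite and >= 0.")
  }
  if (any(!(panel$loq > panel$lod) | !(panel$lod > 0))) {
    abort("Panel limits must satisfy loq > lod > 0 for every element.")
  }
  # every element must cover every class
  cover <- table(panel$element, panel$class)
  if (any(cover != 1)) {
    abort("Every panel element must have exactly one mean per class.")
  }
  invisible(panel)
}

#' Write a panel configuration to YAML
#'
#' Serializes a panel (plus simulation defaults) so a study design can be
#' versioned and re-read with [read_panel()]. The packaged file
#' `system.file("extdata", "insect_panel.yaml", package = "flourprint")`
#' holds the default insect-flour design.
#'
#' @param panel Panel tibble as returned by [insect_panel()].
#' @param path File to write.
#' @param n_per_class Named counts per class.
#' @param within_class_cv Within-class coefficient of variation.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path,
                        n_per_class = default_class_sizes(),
                        within_class_cv = 0.1) {
  check_panel(panel)
  classes <- unique(panel$class)
  elements <- unique(panel$element)
  spec <- list(
    classes = as.list(classes),
    n_per_class = as.list(setNames(as.integer(n_per_class[classes]),
                                   classes)),
    within_class_cv = within_class_cv,
    elements = lapply(elements, function(el) {
      sub <- panel[panel$element == el, ]
      list(
        element = el,
        lod = sub$lod[1],
        loq = sub$loq[1],
        means = as.list(setNames(sub$mean[match(classes, sub$class)],
                                 classes)),
        censor = as.list(setNames(sub$censor[match(classes, sub$class)],
                                  classes))
      )
    })
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read a panel configuration from YAML or JSON
#'
#' @param path File written by [write_panel()] (YAML) or an equivalent JSON
#'   document.
#' @return A list with `panel` (tibble), `n_per_class` (named integer
#'   vector) and `within_class_cv`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("No such panel file: ", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  classes <- unlist(spec$classes)
  panel <- purrr::map_dfr(spec$elements, function(el) {
    tibble::tibble(
      element = el$element,
      class = classes,
      mean = unlist(el$means)[classes],
      lod = el$lod,
      loq = el$loq,
      censor = if (!is.null(el$censor)) {
        unlist(el$censor)[classes]
      } else {
        "observed"
      }
    )
  })
  check_panel(panel)
  list(
    panel = panel,
    n_per_class = setNames(as.integer(unlist(spec$n_per_class)[classes]),
                           classes),
    within_class_cv = spec$within_class_cv
  )
}
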