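# Internal helpers shared across modules.

# Columns every long concentration table must carry.
conc_cols <- c("sample_id", "class", "element", "value")

check_conc <- function(data, flags = FALSE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (long concentration table).")
  }
  need <- conc_cols
  if (flags) need <- c(need, "flag")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "`data` is missing column(s): ", paste(missing, collapse = ", "),
      ". Expected a long concentration table with columns ",
      paste(need, collapse = ", "), "."
    ))
  }
  invisible(data)
}

#' Pivot a long concentration table to the wide samples-by-elements layout
#'
#' The long layout (`sample_id`, `class`, `element`, `value`, optionally
#' `flag`) is the package's exchange format; matrix-based stages (PCA, LDA)
#' work on one row per sample with one column per element.
#'
#' @param data Long concentration table.
#' @return A tibble with columns `sample_id`, `class`, then one numeric
#'   column per element, in the element order of first appearance.
#' @export
#' @examples
#' tbl <- simulate_flours(seed = 1)
#' conc_widen(tbl)
conc_widen <- function(data) {
  check_conc(data)
  elements <- unique(data$element)
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "sample_id", "class", "element", "value"),
    names_from = "element", values_from = "value"
  )
  dplyr::select(wide, "sample_id", "class", dplyr::all_of(elements))
}

#' Pivot a wide samples-by-elements table back to the long layout
#'
#' @param wide Tibble with `sample_id`, `class` and one column per element.
#' @param flags Optional tibble of the same shape holding censor flags.
#' @return A long concentration table; `flag` is `"observed"` when no flag
#'   table is supplied.
#' @export
conc_lengthen <- function(wide, flags = NULL) {
  long <- tidyr::pivot_longer(
    wide,
    cols = -dplyr::all_of(c("sample_id", "class")),
    names_to = "element", values_to = "value"
  )
  if (is.null(flags)) {
    long$flag <- "observed"
  } else {
    flag_long <- tidyr::pivot_longer(
      flags,
      cols = -dplyr::all_of(c("sample_id", "class")),
      names_to = "element", values_to = "flag"
    )
    long <- dplyr::left_join(
      long, flag_long,
      by = c("sample_id", "class", "element")
    )
  }
  long
}

# Extract the numeric matrix (rownames = sample ids) from a wide table.
wide_matrix <- function(wide, elements = NULL) {
  if (is.null(elements)) {
    elements <- setdiff(names(wide), c("sample_id", "class"))
  }
  missing <- setdiff(elements, names(wide))
  if (length(missing) > 0) {
    abort(paste0(
      "Element(s) not present in data: ", paste(missing, collapse = ", ")
    ))
  }
  x <- as.matrix(wide[, elements, drop = FALSE])
  storage.mode(x) <- "double"
  if ("sample_id" %in% names(wide)) rownames(x) <- wide[["sample_id"]]
  x
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  if (positive && x <= 0) abort(paste0("`", name, "` must be > 0."))
  if (nonneg && x < 0) abort(paste0("`", name, "` must be >= 0."))
  invisible(x)
}
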