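# Concentration-table CSV dialect: a values file with header
# sample_id,class,<element>,... and a companion flags file of identical
# shape whose cells are "observed", "<LOQ" or "<LOD". Numeric values are
# always written in the values file, so the pair round-trips losslessly.

#' Write a concentration table to CSV
#'
#' @param data Long concentration table (with `flag`s).
#' @param path Values CSV (wide: `sample_id,class,<element>...`).
#' @param flags_path Optional companion CSV holding the censor marks
#'   (`observed` / `<LOQ` / `<LOD`) cell by cell.
#' @param censored If `TRUE`, censored cells in the values file itself are
#'   replaced by the literal strings `<LOD` / `<LOQ` (human-readable but
#'   lossy; pair with `flags_path` and numeric values for a lossless
#'   round trip).
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(data, path, flags_path = NULL,
                                 censored = FALSE) {
  check_conc(data, flags = TRUE)
  wide <- conc_widen(data)
  mark <- c(observed = "observed", below_loq = "<LOQ", below_lod = "<LOD")
  flags_wide <- tidyr::pivot_wider(
    dplyr::mutate(data, flag = unname(mark[.data$flag])),
    id_cols = c("sample_id", "class"),
    names_from = "element", values_from = "flag"
  )
  if (censored) {
    chr <- dplyr::mutate(
      data,
      value = dplyr::case_when(
        .data$flag == "below_lod" ~ "<LOD",
        .data$flag == "below_loq" ~ "<LOQ",
        TRUE ~ as.character(.data$value)
      )
    )
    values <- tidyr::pivot_wider(
      dplyr::select(chr, "sample_id", "class", "element", "value"),
      names_from = "element", values_from = "value"
    )
    readr::write_csv(values, path)
  } else {
    readr::write_csv(wide, path)
  }
  if (!is.null(flags_path)) readr::write_csv(flags_wide, flags_path)
  invisible(path)
}

#' Read a concentration table from CSV
#'
#' Inverse of [write_concentrations()]. Literal `<LOD` / `<LOQ` strings in
#' the values file are honoured as flags (their numeric value becomes
#' `NA`); a companion flags file takes precedence and preserves numeric
#' values exactly.
#'
#' @param path Values CSV.
#' @param flags_path Optional companion flags CSV.
#' @return Long concentration table.
#' @export
read_concentrations <- function(path, flags_path = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           class = readr::col_character(),
                           .default = readr::col_character()
                         ))
  if (!all(c("sample_id", "class") %in% names(raw))) {
    abort("Values CSV must have `sample_id` and `class` columns.")
  }
  long <- tidyr::pivot_longer(raw, -c("sample_id", "class"),
                              names_to = "element", values_to = "raw")
  long <- dplyr::mutate(
    long,
    flag = dplyr::case_when(
      .data$raw == "<LOD" ~ "below_lod",
      .data$raw == "<LOQ" ~ "below_loq",
      TRUE ~ "observed"
    ),
    value = suppressWarnings(as.numeric(.data$raw))
  )
  long <- dplyr::select(long, "sample_id", "class", "element", "value",
                        "flag")
  if (!is.null(flags_path)) {
    flags_raw <- readr::read_csv(flags_path, show_col_types = FALSE)
    unmark <- c(observed = "observed", "<LOQ" = "below_loq",
                "<LOD" = "below_lod")
    flag_long <- tidyr::pivot_longer(flags_raw, -c("sample_id", "class"),
                                     names_to = "element",
                                     values_to = "mark")
    flag_long <- dplyr::mutate(flag_long,
                               flag2 = unname(unmark[.data$mark]))
    long <- dplyr::left_join(
      dplyr::select(long, -"flag"),
      dplyr::select(flag_long, "sample_id", "class", "element", "flag2"),
      by = c("sample_id", "class", "element")
    )
    long <- dplyr::rename(long, flag = "flag2")
  }
  long
}
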