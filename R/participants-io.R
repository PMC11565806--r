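participant_required_columns <- c(
  "id", "age", "sex", "hair_color", "hair_type", "hair_texture",
  "skin_type"
)

#' Read a participant table (TSV)
#'
#' Reads a tab-delimited participant table with the recommended metadata
#' fields (hair colour/type/texture codes, regrouped Fitzpatrick skin
#' type, age, sex) and the optional ones (melanin-index skin
#' pigmentation, head measurements, per-region trichoscopy metrics with
#' `side_`/`back_` prefixes). Missing optional columns are allowed;
#' missing required columns or invalid ordinal codes raise a schema
#' error.
#'
#' @param path TSV file path (UTF-8, `"."` decimal separator).
#' @return A participant tibble.
#' @export
read_participants <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(participant_required_columns, names(tab))
  if (length(missing) > 0) {
    stop("participant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_participants(tab)
  tab
}

#' Write a participant table (TSV)
#'
#' @param table A participant tibble (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(table, path) {
  validate_participants(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}
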