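#' Table schemas used by the pipeline
#'
#' Required columns and readr column types for each table kind.
#' @keywords internal
table_schemas <- function() {
  list(
    participants = list(
      cols = readr::cols(
        participant_id = readr::col_character(),
        group = readr::col_character(),
        sex = readr::col_character(),
        age = readr::col_double(),
        ses = readr::col_double(),
        .default = readr::col_guess()
      ),
      required = c("participant_id", "group", "sex", "age", "ses")
    ),
    trials = list(
      cols = readr::cols(
        participant_id = readr::col_character(),
        module = readr::col_integer(),
        trait = readr::col_character(),
        identity_id = readr::col_integer(),
        example_id = readr::col_integer(),
        rating = readr::col_integer(),
        rt_ms = readr::col_double(),
        .default = readr::col_guess()
      ),
      required = c("participant_id", "module", "trait", "identity_id",
                   "example_id", "rating", "rt_ms")
    ),
    neurons = list(
      cols = readr::cols(
        neuron_id = readr::col_character(),
        region = readr::col_character(),
        baseline_rate = readr::col_double(),
        identity_id = readr::col_integer(),
        example_id = readr::col_integer(),
        response_rate = readr::col_double(),
        baseline_window_rate = readr::col_double(),
        .default = readr::col_guess()
      ),
      required = c("neuron_id", "region", "baseline_rate", "identity_id",
                   "example_id", "response_rate", "baseline_window_rate")
    ),
    subscales = list(
      cols = readr::cols(
        participant_id = readr::col_character(),
        .default = readr::col_double()
      ),
      required = "participant_id"
    ),
    scores = list(
      cols = readr::cols(
        participant_id = readr::col_character(),
        .default = readr::col_double()
      ),
      required = "participant_id"
    ),
    trait_means = list(
      cols = readr::cols(
        participant_id = readr::col_character(),
        .default = readr::col_double()
      ),
      required = "participant_id"
    )
  )
}

#' Read a pipeline table with schema validation
#'
#' Reads an RFC-4180 CSV, coerces columns to the schema's types,
#' errors on missing required columns, and warns about (but preserves)
#' unknown columns where the schema enumerates its columns.
#'
#' @param path CSV path.
#' @param schema_name One of `"participants"`, `"trials"`, `"neurons"`,
#'   `"subscales"`, `"scores"`, `"trait_means"`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema_name) {
  schemas <- table_schemas()
  if (!schema_name %in% names(schemas)) {
    abort(sprintf("unknown schema `%s`", schema_name),
      class = "traitspace_schema_error"
    )
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "traitspace_schema_error")
  }
  sch <- schemas[[schema_name]]
  tb <- suppressWarnings(
    readr::read_csv(path, col_types = sch$cols, progress = FALSE)
  )
  prob <- readr::problems(tb)
  if (nrow(prob) > 0) {
    abort(
      sprintf("unparseable cell(s) in %s, first at row %d, column %d",
              path, prob$row[1], prob$col[1]),
      class = "traitspace_schema_error"
    )
  }
  missing <- setdiff(sch$required, names(tb))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      class = "traitspace_schema_error"
    )
  }
  named <- setdiff(names(sch$cols$cols), ".default")
  if (length(named) > 1) {
    unknown <- setdiff(names(tb), named)
    if (length(unknown) > 0) {
      warn(sprintf("unknown column(s) preserved: %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  tb
}

#' Write a pipeline table
#'
#' RFC-4180 CSV, UTF-8, header row, '.' decimal separator.
#'
#' @param x Tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

write_dm_csv <- function(dm, path) {
  df <- as.data.frame(unclass(dm))
  df <- cbind(label = rownames(dm), df)
  readr::write_csv(df, path)
  invisible(path)
}
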