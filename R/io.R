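# CSV reading and writing for the three record types. UTF-8, "." decimal
# separator, header row. The vial format is long: one row per vial x interval,
# with n_censored populated only on each vial's final row.

#' Column-mapping schema for external deposits
#'
#' A thin adapter for tables whose column names or factor labels differ from
#' the package's canonical layout (e.g. the archived experimental deposit,
#' whose exact schema is not published). `columns` maps canonical names to the
#' file's names; `levels` optionally recodes factor labels, as named vectors
#' `c(canonical = "file_label", ...)` per factor.
#'
#' @param columns named character vector, canonical -> file column name.
#'   Canonical names missing from the mapping are assumed unchanged.
#' @param levels named list of named character vectors recoding factor labels.
#' @return object of class `table_schema`.
#' @examples
#' sch <- table_schema(columns = c(vial_id = "Vial", deaths = "n_dead"),
#'                     levels = list(sex = c(F = "female", M = "male")))
#' @export
table_schema <- function(columns = character(), levels = list()) {
  stopifnot(is.character(columns), is.list(levels))
  structure(list(columns = columns, levels = levels), class = "table_schema")
}

apply_schema <- function(df, schema, canonical_columns) {
  if (is.null(schema)) return(df)
  stopifnot(inherits(schema, "table_schema"))
  for (canon in names(schema$columns)) {
    file_col <- schema$columns[[canon]]
    if (!file_col %in% names(df)) {
      stop(sprintf("schema maps '%s' to column '%s', which is absent from the file",
                   canon, file_col))
    }
    names(df)[names(df) == file_col] <- canon
  }
  for (fac in names(schema$levels)) {
    if (!fac %in% names(df)) next
    map <- schema$levels[[fac]]
    hit <- match(df[[fac]], map)
    df[[fac]][!is.na(hit)] <- names(map)[hit[!is.na(hit)]]
  }
  df
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read everything as character: "F" must stay a sex label, not a logical;
  # the table constructors coerce numeric columns explicitly
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8", colClasses = "character")
}

#' Read a vial interval table from CSV
#'
#' @param path CSV file in the long format written by [write_vial_table()].
#' @param schema optional [table_schema()] mapping a foreign layout onto the
#'   canonical columns before validation.
#' @return a validated [vial_table()].
#' @export
read_vial_table <- function(path, schema = NULL) {
  df <- read_csv_strict(path)
  df <- apply_schema(df, schema, vial_table_columns())
  vial_table(df)
}

#' Write a vial interval table to CSV
#'
#' Writes the long format [read_vial_table()] accepts; reading the file back
#' reproduces the input exactly.
#'
#' @param records a [vial_table()] (or an empty data.frame for a header-only
#'   file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vial_table <- function(records, path) {
  if (nrow(records) > 0L) records <- vial_table(records)
  write_csv_utf8(records, path, vial_table_columns())
}

#' Read / write fecundity tables
#'
#' @param path CSV file.
#' @param schema optional [table_schema()].
#' @return [fecundity_table()] for the reader; `path` invisibly for the writer.
#' @export
read_fecundity_table <- function(path, schema = NULL) {
  df <- read_csv_strict(path)
  df <- apply_schema(df, schema, fecundity_table_columns())
  fecundity_table(df)
}

#' @rdname read_fecundity_table
#' @param records a [fecundity_table()].
#' @export
write_fecundity_table <- function(records, path) {
  if (nrow(records) > 0L) records <- fecundity_table(records)
  write_csv_utf8(records, path, fecundity_table_columns())
}

#' Read / write line-trait tables
#'
#' @param path CSV file.
#' @param schema optional [table_schema()].
#' @return [line_trait_table()] for the reader; `path` invisibly for the writer.
#' @export
read_line_trait_table <- function(path, schema = NULL) {
  df <- read_csv_strict(path)
  df <- apply_schema(df, schema, line_trait_table_columns())
  line_trait_table(df)
}

#' @rdname read_line_trait_table
#' @param records a [line_trait_table()].
#' @export
write_line_trait_table <- function(records, path) {
  if (nrow(records) > 0L) records <- line_trait_table(records)
  write_csv_utf8(records, path, line_trait_table_columns())
}

write_csv_utf8 <- function(df, path, columns) {
  df <- as.data.frame(df)
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(columns)), columns))
  }
  ok <- tryCatch({
    utils::write.csv(df[, columns, drop = FALSE], path, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Validate a dataset and return the violation report
#'
#' Generic entry point mirroring the per-type validators; currently dispatches
#' on vial tables (the only type with cross-row structure).
#'
#' @param records a `vial_table` or data.frame in vial layout.
#' @return validation report (zero rows iff valid); see [validate_vial_table()].
#' @export
validate_dataset <- function(records) {
  validate_vial_table(records)
}
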