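#' Load and validate a subject table
#'
#' Reads a delimited text file (tab or comma, autodetected from the header
#' line) with one row per subject. Required columns: `id` (unique), `group`
#' (exactly two levels, e.g. patient/control). Recognised numeric columns --
#' `age` (years), `sex` (0 = female, 1 = male; "F"/"M" accepted and recoded),
#' `education` (years), `bmi` (kg/m^2), `mean_fd` (mm), blood measures and
#' cognitive scores -- are validated as finite where present; any additional
#' columns are carried through untouched.
#'
#' @param path Path to a delimited text file with a header row.
#' @return A `data.frame` with class `subject_table` prepended; attribute
#'   `groups` holds the two group levels (sorted).
#' @export
load_subject_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_subject_table(df)
}

#' Validate a subject data frame
#'
#' Applies the schema checks of [load_subject_table()] to an in-memory
#' data frame (as produced by [simulate_cohort()]).
#' @param df A data frame with at least `id` and `group` columns.
#' @return The validated data frame with class `subject_table`.
#' @export
validate_subject_table <- function(df) {
  if (!all(c("id", "group") %in% names(df)))
    stop("subject table must have 'id' and 'group' columns")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate subject ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  groups <- sort(unique(as.character(df$group)))
  if (length(groups) != 2L)
    stop("'group' must have exactly 2 levels, found ", length(groups))
  if ("sex" %in% names(df) && is.character(df$sex)) {
    up <- toupper(trimws(df$sex))
    if (all(up %in% c("F", "M", "0", "1"))) {
      df$sex <- ifelse(up %in% c("M", "1"), 1L, 0L)
    } else stop("'sex' must be coded 0/1 or F/M")
  }
  numeric_cols <- intersect(
    c("age", "sex", "education", "bmi", "mean_fd"), names(df))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) || any(!is.finite(v)))
      stop("column '", col, "' must be numeric and finite")
    df[[col]] <- v
  }
  if ("sex" %in% names(df) && !all(df$sex %in% c(0, 1)))
    stop("'sex' must be coded 0/1")
  class(df) <- c("subject_table", "data.frame")
  attr(df, "groups") <- groups
  df
}

#' Write a subject table as tab-delimited text
#' @param table A subject table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
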