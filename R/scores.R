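#' The bundled 10-test cognitive battery
#'
#' Test specifications for the neuropsychological battery used throughout
#' the package: 10 tests covering 5 cognitive domains. `direction` states
#' whether larger raw scores mean better performance; it is
#' `"lower_better"` exactly for the time-scored Trail-making Tests and
#' `"higher_better"` otherwise. `control_mean`/`control_sd` are the
#' score scales the synthetic generator targets for healthy controls
#' (native test units).
#'
#' @return data frame with one row per test: `test_id`, `name`, `domain`,
#'   `direction`, `units`, `control_mean`, `control_sd`.
#' @export
cognitive_battery <- function() {
  df <- data.frame(
    test_id = c("tmt_a", "tmt_b", "shopping_tour", "number_transcoding",
                "digit_span_fw", "digit_span_bw", "corsi_fw", "corsi_bw",
                "word_list_immediate", "word_list_delayed"),
    name = c("Trail-making Test A", "Trail-making Test B",
             "Imagined Shopping Tour", "Number Transcoding",
             "Digit Span forward", "Digit Span backward",
             "Corsi Block Tapping forward", "Corsi Block Tapping backward",
             "Word List immediate recall", "Word List delayed recall"),
    domain = c("attention_processing_speed", "executive_function",
               "language_semantic_fluency", "language_processing",
               "verbal_working_memory", "verbal_working_memory",
               "visuospatial_working_memory", "visuospatial_working_memory",
               "verbal_episodic_memory", "verbal_episodic_memory"),
    direction = c("lower_better", "lower_better", rep("higher_better", 8)),
    units = c("s", "s", "items", "items", "weighted_items",
              "weighted_items", "weighted_items", "weighted_items",
              "items", "items"),
    control_mean = c(40, 85, 26, 21, 8, 7, 9, 8, 45, 12),
    control_sd   = c(12, 30,  6,  2, 2, 2, 2, 2,  5,  3),
    stringsAsFactors = FALSE
  )
  df
}

#' Look up a single test specification
#'
#' @param test_id test identifier.
#' @param battery battery table, default [cognitive_battery()].
#' @return one-row data frame (a TestSpec).
#' @export
test_spec <- function(test_id, battery = cognitive_battery()) {
  row <- battery[battery$test_id == test_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown test_id '", test_id, "'", call. = FALSE)
  }
  row
}

# +1 if larger raw scores mean better performance, else -1
direction_sign <- function(spec) {
  if (identical(spec$direction, "higher_better")) 1 else -1
}

#' Read a score table
#'
#' Reads a TSV/CSV whose first column is `subject_id` and remaining
#' columns are test scores in native units; empty cells or `NA` mark
#' missing scores. Subjects with a missing value for a test are dropped
#' pairwise for that test only by downstream modeling.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return data frame with `subject_id` plus one numeric column per test.
#' @export
read_score_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  names(df)[1] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  for (j in seq_along(df)[-1]) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write a score table as TSV
#'
#' @param scores score data frame (first column `subject_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' Reads a TSV/CSV whose first column is `subject_id`. Numeric columns
#' (age, ISCED education level, interval since treatment, intervention
#' counts, lesion volumes) are kept numeric; categorical columns (sex,
#' IDH status, grade, recurrence, tumor location) stay character.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return data frame with `subject_id` plus covariate columns.
#' @export
read_covariate_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  names(df)[1] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  df
}
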