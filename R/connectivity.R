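#' Construct a connectivity matrix object
#'
#' A structural connectivity matrix holds nonnegative fiber counts between
#' all pairs of parcellation nodes. It must be exactly symmetric; the main
#' diagonal is meaningless and is forced to zero (with a warning if it
#' held nonzero values).
#'
#' @param values square numeric matrix of nonnegative fiber counts.
#' @param subject_id subject identifier string.
#' @param lesion_side optional lesion laterality, one of `"L"`, `"R"`,
#'   `"bilateral"`, `"none"`.
#' @param parcellation optional `parcellation`; when given, the matrix
#'   dimension must match its node count.
#' @return a `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, subject_id = "subject",
                                lesion_side = NULL, parcellation = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("connectivity matrix must be square, got ",
         nrow(values), " x ", ncol(values), call. = FALSE)
  }
  if (!is.null(parcellation) && nrow(values) != nrow(parcellation)) {
    stop("matrix dimension ", nrow(values),
         " does not match parcellation node count ", nrow(parcellation),
         call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("connectivity matrix contains missing or non-finite entries",
         call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative fiber count at (", bad[1], ",", bad[2], ")",
         call. = FALSE)
  }
  asym <- abs(values - t(values))
  if (any(asym > 0)) {
    worst <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    worst <- sort(worst)
    stop("matrix is not symmetric; worst mismatch at (",
         worst[1], ",", worst[2], "): ",
         values[worst[1], worst[2]], " vs ", values[worst[2], worst[1]],
         call. = FALSE)
  }
  if (any(diag(values) != 0)) {
    warning("nonzero diagonal entries set to zero (self-connections are ",
            "meaningless)", call. = FALSE)
    diag(values) <- 0
  }
  dimnames(values) <- NULL
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            subject_id = as.character(subject_id),
            lesion_side = if (is.null(lesion_side)) NA_character_
                          else match.arg(lesion_side,
                                         c("L", "R", "bilateral", "none")))
}

# strip class/attributes, return the plain numeric matrix
connectivity_values <- function(m) {
  v <- unclass(m)
  attr(v, "subject_id") <- NULL
  attr(v, "lesion_side") <- NULL
  v
}

#' Read a connectivity matrix from delimited text
#'
#' Reads a square numeric matrix (TSV or CSV), with an optional header
#' row/column of node ids, and validates it against the parcellation:
#' exact symmetry is required, entries must be nonnegative, and a nonzero
#' diagonal is zeroed with a warning. The subject id defaults to the file
#' name without extension.
#'
#' @param path path to the matrix file.
#' @param parcellation a `parcellation` object.
#' @param subject_id subject identifier; default taken from the file name.
#' @param lesion_side optional lesion laterality (see
#'   [connectivity_matrix()]).
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return a `connectivity_matrix`.
#' @export
read_connectivity_matrix <- function(path, parcellation,
                                     subject_id = NULL, lesion_side = NULL,
                                     sep = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  # an empty leading cell (row-name corner) or any non-numeric token
  # marks a header line
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- read.delim(path, sep = sep, header = has_header,
                   row.names = if (has_header) 1L else NULL,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df)
  if (!is.numeric(values)) {
    stop("non-numeric entries in ", path, call. = FALSE)
  }
  connectivity_matrix(values, subject_id = subject_id,
                      lesion_side = lesion_side,
                      parcellation = parcellation)
}

#' Write a connectivity matrix as TSV
#'
#' Writes the square fiber-count matrix with node ids as header row and
#' first column, so that [read_connectivity_matrix()] round-trips
#' bit-identically for integer matrices.
#'
#' @param m a `connectivity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(m, path) {
  v <- connectivity_values(m)
  n <- nrow(v)
  dimnames(v) <- list(seq_len(n), seq_len(n))
  write.table(v, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  v <- connectivity_values(x)
  cat("Connectivity matrix for subject '", attr(x, "subject_id"), "': ",
      nrow(v), " x ", ncol(v), " fiber counts (median ",
      stats::median(v[upper.tri(v)]), ", max ", max(v), ")\n", sep = "")
  side <- attr(x, "lesion_side")
  if (!is.na(side)) cat("  lesion side:", side, "\n")
  invisible(x)
}
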