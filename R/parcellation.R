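#' The seven canonical resting-state networks
#'
#' Closed vocabulary of network labels used by parcellations in this
#' package, following the 7-network cortical taxonomy (visual, somatomotor,
#' dorsal attention, ventral attention, limbic, frontal control, default
#' mode).
#'
#' @export
CORTICAL_NETWORKS <- c("visual", "somatomotor", "dorsal_attention",
                       "ventral_attention", "limbic", "control",
                       "default_mode")

new_parcellation <- function(df) {
  structure(df, class = c("parcellation", "data.frame"))
}

validate_parcellation <- function(df, file = "<parcellation>") {
  required <- c("node_id", "hemisphere", "network", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("parcellation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$node_id <- as.integer(df$node_id)
  n <- nrow(df)
  if (n < 2) stop("parcellation must contain at least 2 nodes", call. = FALSE)
  if (anyDuplicated(df$node_id)) {
    stop("duplicate node_id(s) in ", file, ": ",
         paste(unique(df$node_id[duplicated(df$node_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(sort(df$node_id), seq_len(n))) {
    stop("node_ids must be contiguous 1..", n, " in ", file, call. = FALSE)
  }
  if (!all(df$hemisphere %in% c("L", "R"))) {
    bad <- which(!df$hemisphere %in% c("L", "R"))
    stop("unknown hemisphere in row(s) ", paste(bad, collapse = ", "),
         " of ", file, " (must be L or R)", call. = FALSE)
  }
  bad_net <- which(!df$network %in% CORTICAL_NETWORKS)
  if (length(bad_net)) {
    stop("unknown network name(s) in row(s) ",
         paste(bad_net, collapse = ", "), " of ", file, ": ",
         paste(unique(df$network[bad_net]), collapse = ", "),
         "; must be one of ", paste(CORTICAL_NETWORKS, collapse = ", "),
         call. = FALSE)
  }
  new_parcellation(df[, required])
}

#' Read a parcellation table
#'
#' Reads a tab- or comma-delimited node table with header columns
#' `node_id`, `hemisphere`, `network`, `label`. Node order is preserved as
#' file order; node ids must be unique and contiguous starting at 1, and
#' network names must belong to [CORTICAL_NETWORKS].
#'
#' @param path path to a delimited text file.
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return a `parcellation` data frame.
#' @seealso [synthetic_parcellation()] for the bundled 100-node fixture.
#' @export
read_parcellation <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  validate_parcellation(df, file = path)
}

#' Write a parcellation table to TSV
#'
#' @param parcellation a `parcellation` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parcellation, path) {
  write.table(as.data.frame(parcellation), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic 100-node, 7-network parcellation
#'
#' Builds an ordered node table emulating a whole-cortex functional
#' parcellation at its lowest resolution: `n_per_hemisphere` nodes per
#' hemisphere (default 50, i.e. 100 nodes total), each hemisphere covering
#' all 7 canonical networks. Left-hemisphere nodes come first. Network
#' sizes per hemisphere are fixed proportions of the hemisphere size so
#' that every network is non-empty on each side.
#'
#' @param n_per_hemisphere nodes per hemisphere (>= 7).
#' @return a `parcellation` data frame with `2 * n_per_hemisphere` rows.
#' @export
synthetic_parcellation <- function(n_per_hemisphere = 50L) {
  n_per_hemisphere <- as.integer(n_per_hemisphere)
  if (n_per_hemisphere < 7L) {
    stop("need at least 7 nodes per hemisphere (one per network)",
         call. = FALSE)
  }
  # relative network sizes loosely follow cortical surface shares
  w <- c(visual = 9, somatomotor = 8, dorsal_attention = 7,
         ventral_attention = 7, limbic = 5, control = 6, default_mode = 8)
  sizes <- setNames(pmax(1L, floor(w / sum(w) * n_per_hemisphere)),
                    names(w))
  # distribute the remainder over the largest networks
  while (sum(sizes) < n_per_hemisphere) {
    i <- which.max(w / sizes)
    sizes[i] <- sizes[i] + 1L
  }
  while (sum(sizes) > n_per_hemisphere) {
    i <- which.min(w / sizes)
    sizes[i] <- sizes[i] - 1L
  }
  one_side <- function(hemi) {
    net <- rep(names(sizes), times = sizes)
    data.frame(hemisphere = hemi, network = net,
               label = paste(hemi, net, ave(seq_along(net), net,
                                            FUN = seq_along), sep = "_"),
               stringsAsFactors = FALSE)
  }
  df <- rbind(one_side("L"), one_side("R"))
  df <- cbind(node_id = seq_len(nrow(df)), df)
  validate_parcellation(df)
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation:", nrow(x), "nodes (",
      sum(x$hemisphere == "L"), "L /", sum(x$hemisphere == "R"), "R ),",
      length(unique(x$network)), "networks\n")
  invisible(x)
}
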