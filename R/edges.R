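#' Edge universe of a parcellation
#'
#' For an `N`-node parcellation the connectivity matrix has `N * (N - 1)`
#' informative off-diagonal entries (the convention used for all
#' "% of possible edges" reporting), corresponding to `N * (N - 1) / 2`
#' unique undirected edges. Screening and mapping operate on unique edges
#' (upper triangle, `i < j`, row-major order) and multiply by 2 where
#' directed-entry units are reported.
#'
#' @param n_nodes number of nodes (>= 2).
#' @return list with `n_nodes`, `directed_entry_count`, `unique_edge_count`
#'   and `pairs`, a `unique_edge_count x 2` integer matrix of 1-based
#'   `(i, j)` node pairs in flat edge-index order.
#' @export
edge_universe <- function(n_nodes) {
  n <- as.integer(n_nodes)
  if (is.na(n) || n < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  list(n_nodes = n,
       directed_entry_count = n * (n - 1L),
       unique_edge_count = (n * (n - 1L)) %/% 2L,
       pairs = cbind(i = i, j = j))
}

#' Count valid off-diagonal matrix entries
#'
#' The number of informative entries of an `N x N` connectivity matrix
#' after removing the meaningless main diagonal: `N * (N - 1)`. For the
#' default 100-node parcellation this is 9900, the denominator used for
#' all percentage-of-possible-edges reporting.
#'
#' @param parcellation a `parcellation` object (or an integer node count).
#' @return integer `N * (N - 1)`.
#' @export
count_valid_entries <- function(parcellation) {
  n <- if (inherits(parcellation, "parcellation") ||
           is.data.frame(parcellation)) nrow(parcellation)
       else as.integer(parcellation)
  if (is.na(n) || n < 2L) stop("invalid parcellation", call. = FALSE)
  n * (n - 1L)
}

#' Flat edge index of a node pair
#'
#' Maps 1-based node pairs `(i, j)`, `i != j`, to the flat index of the
#' unique undirected edge in row-major upper-triangle order; `(j, i)` maps
#' to the same index as `(i, j)`.
#'
#' @param n_nodes number of nodes.
#' @param i,j node ids (vectors of equal length).
#' @return integer vector of flat edge indices in `1..N(N-1)/2`.
#' @export
edge_index <- function(n_nodes, i, j) {
  n <- as.integer(n_nodes)
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo < 1L | hi > n | lo == hi)) {
    stop("node pairs must satisfy 1 <= i != j <= ", n, call. = FALSE)
  }
  as.integer((lo - 1L) * n - (lo * (lo - 1L)) %/% 2L + (hi - lo))
}

#' Flatten connectivity matrices to a subjects x edges table
#'
#' One row per subject, one column per unique undirected edge (upper
#' triangle, `i < j`, row-major). All matrices must share one
#' parcellation dimension.
#'
#' @param matrices a list of `connectivity_matrix` objects (or plain
#'   symmetric matrices).
#' @return numeric matrix with subject ids as row names and edge columns
#'   named `"i_j"`; the edge universe is attached as attribute
#'   `"edge_universe"`.
#' @seealso [unvectorize_edges()] for the inverse.
#' @export
vectorize_edges <- function(matrices) {
  if (inherits(matrices, "connectivity_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  dims <- vapply(matrices, function(m) nrow(connectivity_values(m)), 1L)
  if (length(unique(dims)) != 1L) {
    stop("matrices have mixed dimensions: ",
         paste(unique(dims), collapse = ", "), call. = FALSE)
  }
  eu <- edge_universe(dims[1])
  flat <- eu$pairs[, "i"] + (eu$pairs[, "j"] - 1L) * eu$n_nodes
  out <- t(vapply(matrices,
                  function(m) connectivity_values(m)[flat],
                  numeric(eu$unique_edge_count)))
  rownames(out) <- vapply(matrices, function(m) {
    id <- attr(m, "subject_id")
    if (is.null(id)) "" else id
  }, "")
  colnames(out) <- paste(eu$pairs[, "i"], eu$pairs[, "j"], sep = "_")
  attr(out, "edge_universe") <- eu
  out
}

#' Rebuild a symmetric matrix from a flat edge vector
#'
#' @param edges numeric vector of length `N(N-1)/2` in flat edge order.
#' @param n_nodes number of nodes.
#' @return symmetric `N x N` matrix with zero diagonal.
#' @export
unvectorize_edges <- function(edges, n_nodes) {
  eu <- edge_universe(n_nodes)
  if (length(edges) != eu$unique_edge_count) {
    stop("edge vector has length ", length(edges), ", expected ",
         eu$unique_edge_count, call. = FALSE)
  }
  m <- matrix(0, eu$n_nodes, eu$n_nodes)
  m[cbind(eu$pairs[, "i"], eu$pairs[, "j"])] <- edges
  m[cbind(eu$pairs[, "j"], eu$pairs[, "i"])] <- edges
  m
}
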