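# Plain-text input/output: TSV matrices, graph files (dense adjacency or
# edge list), and JSON run configurations.

#' Write / read a numeric matrix as TSV
#'
#' Full-precision, lossless round trip with a header row of column names.
#'
#' @param path file path.
#' @param matrix numeric matrix.
#' @param names optional column names.
#' @return \code{read_matrix} returns the matrix.
#' @export
write_matrix <- function(path, matrix, names = colnames(matrix)) {
  m <- as.matrix(matrix)
  if (is.null(names)) names <- paste0("V", seq_len(ncol(m)))
  colnames(m) <- names
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "numeric")
  as.matrix(df)
}

#' Read a graph as a dense adjacency or an edge list
#'
#' Dense form: p x p 0/1 TSV (symmetry enforced).  Edge-list form: TSV
#' with columns \code{node_i}, \code{node_j} and optionally \code{belief};
#' \code{p} must then be supplied.
#'
#' @param path file path.
#' @param p number of nodes (edge-list form only).
#' @return list with \code{adjacency} and (edge lists with a belief
#'   column) \code{belief}.
#' @export
read_graph <- function(path, p = NULL) {
  head1 <- utils::read.table(path, header = TRUE, sep = "\t", nrows = 1,
                             check.names = FALSE)
  if (all(c("node_i", "node_j") %in% names(head1))) {
    el <- utils::read.table(path, header = TRUE, sep = "\t")
    if (is.null(p)) stop("p is required for edge-list graphs")
    A <- matrix(0L, p, p)
    K <- matrix(0, p, p)
    for (r in seq_len(nrow(el))) {
      i <- el$node_i[r]
      j <- el$node_j[r]
      A[i, j] <- 1L
      A[j, i] <- 1L
      if ("belief" %in% names(el)) {
        K[i, j] <- el$belief[r]
        K[j, i] <- el$belief[r]
      }
    }
    return(list(adjacency = A,
                belief = if ("belief" %in% names(el)) K else NULL))
  }
  A <- read_matrix(path)
  if (nrow(A) != ncol(A) || !isTRUE(all.equal(unname(A), unname(t(A)))))
    stop("graph adjacency must be square and symmetric")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0/1")
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  list(adjacency = A, belief = NULL)
}

#' Write / read a run configuration as JSON
#'
#' @param config named list of settings (scalars, vectors, nested lists).
#' @param path file path.
#' @return \code{read_config} returns the list; round trips are lossless
#'   for the scalar/vector settings used by \code{\link{run_replicates}}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
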