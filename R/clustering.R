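#' Global clustering coefficient of an undirected simple graph
#'
#' Computes the global clustering coefficient (transitivity)
#' \deqn{\phi = \frac{\mathrm{trace}(G^3)}{\|G^2\| - \mathrm{trace}(G^2)},}
#' where \eqn{G} is the adjacency matrix, \eqn{\|M\|} denotes the sum of all
#' entries of \eqn{M}, \eqn{\mathrm{trace}(G^3)} is six times the number of
#' triangles and \eqn{\|G^2\| - \mathrm{trace}(G^2)} is twice the number of
#' triples (open or closed).
#'
#' @param graph Either a symmetric 0/1 adjacency matrix with zero diagonal, or
#'   a two-column matrix/data.frame of integer node indices (an undirected
#'   edge list, 0- or 1-based; see [read_edgelist()]).
#' @return The clustering coefficient, a number in \eqn{[0, 1]}.
#' @examples
#' K3 <- matrix(1, 3, 3) - diag(3)
#' clustering_coefficient(K3)  # 1: fully clustered
#' @export
clustering_coefficient <- function(graph) {
  G <- as_adjacency(graph)
  G2 <- G %*% G
  G3 <- G2 %*% G
  denom <- sum(G2) - sum(diag(G2))
  if (denom == 0)
    stop("graph has no paths of length two; clustering coefficient undefined",
         call. = FALSE)
  sum(diag(G3)) / denom
}

# Coerce an adjacency matrix or an edge list to a validated dense adjacency
# matrix.
as_adjacency <- function(graph) {
  if (is.data.frame(graph)) graph <- as.matrix(graph)
  if (!is.matrix(graph)) stop("graph must be a matrix or data.frame", call. = FALSE)
  looks_adjacency <- nrow(graph) == ncol(graph) && all(graph %in% c(0, 1)) &&
    all(diag(graph) == 0) && isTRUE(all.equal(graph, t(graph)))
  if (ncol(graph) == 2L && !looks_adjacency) {
    return(edgelist_to_adjacency(graph))
  }
  if (nrow(graph) != ncol(graph))
    stop("adjacency matrix must be square", call. = FALSE)
  if (!all(graph %in% c(0, 1)))
    stop("adjacency matrix must be 0/1", call. = FALSE)
  if (any(diag(graph) != 0))
    stop("self-loops are not allowed (non-zero diagonal)", call. = FALSE)
  if (!isTRUE(all.equal(graph, t(graph))))
    stop("adjacency matrix must be symmetric (undirected graph)", call. = FALSE)
  storage.mode(graph) <- "numeric"
  graph
}

edgelist_to_adjacency <- function(el) {
  storage.mode(el) <- "numeric"
  if (any(!is.finite(el)) || any(el != round(el)))
    stop("edge list must contain integer node indices", call. = FALSE)
  if (min(el) == 0) el <- el + 1  # accept 0-based input
  if (any(el[, 1] == el[, 2]))
    stop("self-loops are not allowed in the edge list", call. = FALSE)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  if (anyDuplicated(key))
    stop("duplicate edges are not allowed in the edge list", call. = FALSE)
  nv <- max(el)
  G <- matrix(0, nv, nv)
  G[el] <- 1
  G[el[, 2:1, drop = FALSE]] <- 1
  G
}

#' Read an undirected edge list from a text file
#'
#' The expected dialect is whitespace-separated integer node pairs, one edge
#' per line, 0- or 1-based, undirected. Duplicate edges and self-loops are
#' rejected.
#'
#' @param path Path to the edge-list file.
#' @return A two-column integer matrix of (1-based) node indices.
#' @export
read_edgelist <- function(path) {
  el <- as.matrix(utils::read.table(path, header = FALSE,
                                    col.names = c("from", "to")))
  if (ncol(el) != 2L) stop("edge list must have two columns", call. = FALSE)
  storage.mode(el) <- "integer"
  if (min(el) == 0L) el <- el + 1L
  el
}
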