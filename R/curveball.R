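#' One curveball trade between two rows
#'
#' The elementary move of the curveball algorithm: given the per-row sets
#' of interaction partners (column indices), pick up the partners exclusive
#' to row `i` and exclusive to row `j`, pool them, and deal them back at
#' random so that each row keeps its original number of partners. Shared
#' partners never move, so both row degrees and the multiset of column
#' memberships — hence all column degrees — are preserved exactly. When the
#' two rows have no exclusive partners the trade is a no-op.
#'
#' The caller owns the RNG state: seed before use for reproducibility.
#'
#' @param rowsets list of integer vectors, one per row, each the set of
#'   column indices that row interacts with.
#' @param i,j distinct row indices to trade between.
#' @return The updated `rowsets` list.
#' @export
curveball_trade <- function(rowsets, i, j) {
  if (i == j) stop("trade requires two distinct rows")
  si <- rowsets[[i]]; sj <- rowsets[[j]]
  shared <- intersect(si, sj)
  pool <- c(setdiff(si, shared), setdiff(sj, shared))
  n_i <- length(si) - length(shared)
  if (length(pool) == 0L || n_i == 0L || n_i == length(pool))
    return(rowsets)                      # nothing exclusive to exchange
  take <- sample(pool, n_i)
  rowsets[[i]] <- c(shared, take)
  rowsets[[j]] <- c(shared, setdiff(pool, take))
  rowsets
}

#' Degree-preserving randomization of a layer (curveball algorithm)
#'
#' Samples from the configuration-model null ensemble: binary matrices
#' with exactly the observed row and column degree sequences. Repeatedly
#' applies [curveball_trade()] to uniformly chosen row pairs, then
#' recompiles the presence/absence matrix from the traded partner lists.
#' Row and column sums of the output equal the input's exactly, for any
#' number of trades; `n_trades` only controls mixing. Zero-degree rows and
#' columns participate trivially (empty partner sets) and remain zero.
#'
#' @param layer a `bipartite_layer`.
#' @param n_trades number of elementary trades; default `5 * max(m, p)`,
#'   the usual mixing recommendation for the algorithm.
#' @param seed integer seed; required, so every null replicate is
#'   reproducible.
#' @return A `bipartite_layer` with the same labels and name, identical
#'   row/column degree sequences, and shuffled interaction structure.
#' @examples
#' pr <- planted_pair(n_rows = 10, n_cols = 10, seed = 1)
#' r <- curveball_randomize(pr$pair$layer1, seed = 99)
#' all(rowSums(r$incidence) == rowSums(pr$pair$layer1$incidence))
#' @export
curveball_randomize <- function(layer, n_trades = NULL, seed) {
  stopifnot(inherits(layer, "bipartite_layer"))
  if (missing(seed)) stop("curveball_randomize requires a seed")
  m <- nrow(layer$incidence); p <- ncol(layer$incidence)
  if (is.null(n_trades)) n_trades <- 5L * max(m, p)
  if (n_trades < 1L) stop("n_trades must be >= 1")
  if (m < 2L) return(layer)              # a single row cannot trade
  inc0 <- layer$incidence
  rowsets <- lapply(seq_len(m), function(r) which(inc0[r, ] == 1))
  local_seed(seed)
  for (t in seq_len(n_trades)) {
    ij <- sample.int(m, 2L)
    rowsets <- curveball_trade(rowsets, ij[1L], ij[2L])
  }
  inc <- matrix(0, m, p, dimnames = dimnames(layer$incidence))
  for (r in seq_len(m)) inc[r, rowsets[[r]]] <- 1
  bipartite_layer(inc, name = layer$name)
}
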