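#' Generate a planted-module pair of bipartite layers
#'
#' Seeded generator of two aligned bipartite layers with known (planted)
#' module structure, used to benchmark every stage of the co-structure
#' pipeline without real data. Layer 1 is drawn from a k-block bipartite
#' stochastic block model: row and column species are assigned to
#' `k_modules` blocks (sizes as equal as possible, remainders spread
#' deterministically over the first blocks) and each row-column pair
#' interacts with probability `p_in` inside a shared block, `p_out`
#' across blocks. Layer 2 uses the same block assignment for a fraction
#' `congruence` of species (per guild, the first `round(congruence * n)`
#' in label order; the rest are re-assigned uniformly at random), then its
#' incidence is drawn independently from the block model. Finally a
#' fraction `zero_frac_rows_l2` of row species (uniformly chosen) have
#' their layer-2 row zeroed, emulating species that interact in only one
#' layer — as in assemblages where many of one guild never appear in the
#' second network.
#'
#' The planted partitions record the block assignments (after
#' re-assignment, before zeroing) over all `n_rows + n_cols` species of
#' each layer. A species that happens to draw no interactions still
#' carries its planted block; detectors will place it in a singleton
#' instead, which bounds attainable recovery scores.
#'
#' @param n_rows,n_cols species counts per guild. Defaults 60 x 60.
#' @param k_modules number of planted blocks (default 4);
#'   must not exceed `min(n_rows, n_cols)`.
#' @param p_in,p_out within-/between-block interaction probabilities
#'   (defaults 0.4 and 0.02); `p_in > p_out` is required.
#' @param congruence fraction of species whose block is identical in the
#'   two layers (default 0.9).
#' @param zero_frac_rows_l2 fraction of row species zeroed out in layer 2
#'   (default 0; 0.46 emulates an assemblage where nearly half the row
#'   guild never interacts in the second layer).
#' @param seed integer seed; required.
#' @return List with `pair` (a [multilayer_pair()]), `partition1`,
#'   `partition2` (planted `network_partition`s) and the per-guild block
#'   assignments.
#' @examples
#' pp <- planted_pair(seed = 1)
#' pp$pair
#' nmi(confusion(pp$partition1, pp$partition2))
#' @export
planted_pair <- function(n_rows = 60, n_cols = 60, k_modules = 4,
                         p_in = 0.4, p_out = 0.02, congruence = 0.9,
                         zero_frac_rows_l2 = 0, seed) {
  if (missing(seed)) stop("planted_pair requires a seed")
  if (k_modules > min(n_rows, n_cols))
    stop("k_modules must be <= min(n_rows, n_cols)")
  if (!(p_in > p_out)) stop("p_in must exceed p_out")
  if (congruence < 0 || congruence > 1 || zero_frac_rows_l2 < 0 ||
      zero_frac_rows_l2 > 1)
    stop("congruence and zero_frac_rows_l2 must lie in [0, 1]")
  local_seed(seed)
  rows <- sprintf("r%03d", seq_len(n_rows))
  cols <- sprintf("c%03d", seq_len(n_cols))
  # equal-as-possible block sizes, deterministic: blocks cycle over labels
  rb1 <- rep(seq_len(k_modules), length.out = n_rows)
  cb1 <- rep(seq_len(k_modules), length.out = n_cols)
  redraw <- function(b, congruence) {
    n <- length(b)
    keep <- seq_len(round(congruence * n))
    out <- b
    idx <- setdiff(seq_len(n), keep)
    if (length(idx)) out[idx] <- sample.int(k_modules, length(idx), replace = TRUE)
    out
  }
  rb2 <- redraw(rb1, congruence)
  cb2 <- redraw(cb1, congruence)
  draw <- function(rb, cb) {
    pmat <- ifelse(outer(rb, cb, "=="), p_in, p_out)
    inc <- (matrix(stats::runif(length(pmat)), nrow(pmat)) < pmat) + 0
    dimnames(inc) <- list(rows, cols)
    inc
  }
  inc1 <- draw(rb1, cb1)
  inc2 <- draw(rb2, cb2)
  if (zero_frac_rows_l2 > 0) {
    nz <- round(zero_frac_rows_l2 * n_rows)
    if (nz > 0) inc2[sample.int(n_rows, nz), ] <- 0
  }
  pair <- multilayer_pair(bipartite_layer(inc1, name = "layer1"),
                          bipartite_layer(inc2, name = "layer2"))
  planted <- function(rb, cb) {
    memb <- c(rb, cb)
    names(memb) <- c(rows, cols)
    as_partition(memb)
  }
  list(pair = pair,
       partition1 = planted(rb1, cb1),
       partition2 = planted(rb2, cb2),
       blocks = list(rows_l1 = rb1, cols_l1 = cb1, rows_l2 = rb2, cols_l2 = cb2))
}

#' Construct a pair of layers realizing given degree sequences
#'
#' Builds, for each layer, a binary bipartite matrix whose row and column
#' sums equal the requested degree sequences exactly, by the bipartite
#' Havel-Hakimi greedy fill (largest remaining row degree connects to the
#' columns of largest remaining capacity), then applies seeded curveball
#' shuffles so the realization is not the deterministic greedy one.
#' Feasibility is checked by the Gale-Ryser condition; infeasible
#' sequences raise an error naming the first violated partial sum.
#'
#' @param row_degrees_1,col_degrees_1 degree sequences of layer 1.
#' @param row_degrees_2,col_degrees_2 degree sequences of layer 2 (must
#'   have the same lengths as layer 1's: the layers share both guilds).
#' @param seed integer seed; required.
#' @return A [multilayer_pair()] whose layers realize the sequences.
#' @examples
#' p <- degree_matched_pair(c(1, 1), c(1, 1), c(2, 0), c(1, 1), seed = 1)
#' rowSums(p$layer2$incidence)
#' @export
degree_matched_pair <- function(row_degrees_1, col_degrees_1,
                                row_degrees_2, col_degrees_2, seed) {
  if (missing(seed)) stop("degree_matched_pair requires a seed")
  if (length(row_degrees_1) != length(row_degrees_2) ||
      length(col_degrees_1) != length(col_degrees_2))
    stop("the two layers must share both guilds (equal sequence lengths)")
  rows <- sprintf("r%03d", seq_along(row_degrees_1))
  cols <- sprintf("c%03d", seq_along(col_degrees_1))
  l1 <- realize_bipartite(row_degrees_1, col_degrees_1)
  l2 <- realize_bipartite(row_degrees_2, col_degrees_2)
  dimnames(l1) <- dimnames(l2) <- list(rows, cols)
  pair <- multilayer_pair(
    curveball_randomize(bipartite_layer(l1, name = "layer1"), seed = seed),
    curveball_randomize(bipartite_layer(l2, name = "layer2"), seed = seed + 1L))
  pair
}

# Gale-Ryser feasibility + greedy Havel-Hakimi realization of a bipartite
# degree sequence; returns the 0/1 matrix or errors if infeasible
realize_bipartite <- function(rd, cd) {
  rd <- as.integer(rd); cd <- as.integer(cd)
  if (any(rd < 0) || any(cd < 0)) stop("degrees must be non-negative")
  if (any(rd > length(cd)) || any(cd > length(rd)))
    stop("a degree exceeds the size of the opposite guild")
  if (sum(rd) != sum(cd))
    stop("degree sums differ between guilds (", sum(rd), " vs ", sum(cd), ")")
  rs <- sort(rd, decreasing = TRUE)
  for (k in seq_along(rs)) {
    lhs <- sum(rs[seq_len(k)])
    rhs <- sum(pmin(cd, k))
    if (lhs > rhs)
      stop("Gale-Ryser condition fails at k = ", k,
           ": sum of top row degrees ", lhs, " > ", rhs)
  }
  m <- length(rd); p <- length(cd)
  inc <- matrix(0, m, p)
  cap <- cd
  for (i in order(rd, decreasing = TRUE)) {
    if (rd[i] == 0L) next
    targets <- order(cap, decreasing = TRUE)[seq_len(rd[i])]
    if (cap[targets[rd[i]]] <= 0L) stop("greedy fill failed; sequence not graphical")
    inc[i, targets] <- 1
    cap[targets] <- cap[targets] - 1L
  }
  stopifnot(all(colSums(inc) == cd), all(rowSums(inc) == rd))
  inc
}
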