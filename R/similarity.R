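#' Confusion matrix of two partitions over the same species
#'
#' Cross-tabulates two module classifications of the same node set: entry
#' `N[i, j]` is the number of species assigned to module `i` of the first
#' partition and module `j` of the second. Row sums are the module sizes of
#' the first partition, column sums those of the second, and the grand
#' total `N` is the number of shared species.
#'
#' @param partition_h,partition_v `network_partition` objects (or named
#'   membership vectors) over the identical node set; order may differ,
#'   alignment is by label.
#' @return Object of class `partition_confusion`: list with matrix `n_ij`,
#'   `row_sums`, `col_sums` and total `n`.
#' @export
confusion <- function(partition_h, partition_v) {
  mh <- member_vector(partition_h)
  mv <- member_vector(partition_v)
  if (!setequal(names(mh), names(mv))) {
    diffs <- c(setdiff(names(mh), names(mv)), setdiff(names(mv), names(mh)))
    stop("partitions cover different node sets; differing nodes: ",
         paste(utils::head(diffs, 10L), collapse = ", "),
         if (length(diffs) > 10L) sprintf(" (and %d more)", length(diffs) - 10L))
  }
  mv <- mv[names(mh)]
  tab <- table(mh, mv)
  n_ij <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                 dimnames = list(module_h = rownames(tab), module_v = colnames(tab)))
  structure(list(n_ij = n_ij, row_sums = rowSums(n_ij), col_sums = colSums(n_ij),
                 n = sum(n_ij)),
            class = "partition_confusion")
}

member_vector <- function(x) {
  m <- if (inherits(x, "network_partition")) x$membership else x
  if (is.null(names(m))) stop("membership must be named by node label")
  m
}

#' Normalized mutual information of two module classifications
#'
#' Measures how well the module assignment in one layer explains the
#' assignment in the other. With confusion matrix `N` (see [confusion()]),
#' module sizes `N_i.`, `N_.j` and total `N`:
#' \deqn{I(H,V) = \frac{-2 \sum_{ij} N_{ij} \log\!\big(N_{ij} N / (N_{i.} N_{.j})\big)}
#'   {\sum_i N_{i.} \log(N_{i.}/N) + \sum_j N_{.j} \log(N_{.j}/N)}}
#' with `0 log 0 = 0` (zero cells are skipped) and natural logarithms (the
#' base cancels). `I = 1` when the two classifications coincide and
#' `I = 0` when they are statistically independent
#' (`N_ij = N_i. N_.j / N` everywhere).
#'
#' When both partitions are the trivial one-module classification the
#' normalization is 0/0: the value 1 is returned if the partitions are
#' then identical (they necessarily are on the same node set), matching
#' the coincidence limit; any other degenerate combination raises an
#' error rather than silently returning 0.
#'
#' @param conf a `partition_confusion`, or a plain counts matrix.
#' @return The normalized mutual information, a number in \[0, 1\].
#' @examples
#' nmi(matrix(c(3, 0, 0, 2), 2))   # identical classifications: 1
#' nmi(matrix(1, 2, 2))            # independent classifications: 0
#' @export
nmi <- function(conf) {
  N_ij <- if (inherits(conf, "partition_confusion")) conf$n_ij else as.matrix(conf)
  if (any(N_ij < 0) || sum(N_ij) < 1) stop("confusion matrix must be non-negative with N >= 1")
  N <- sum(N_ij)
  Ni <- rowSums(N_ij)
  Nj <- colSums(N_ij)
  nz <- which(N_ij > 0, arr.ind = TRUE)
  num <- -2 * sum(N_ij[nz] * log(N_ij[nz] * N / (Ni[nz[, 1L]] * Nj[nz[, 2L]])))
  den <- sum(Ni[Ni > 0] * log(Ni[Ni > 0] / N)) + sum(Nj[Nj > 0] * log(Nj[Nj > 0] / N))
  if (den == 0) {
    # both margins trivial: single module on each side
    if (nrow(N_ij) == 1L && ncol(N_ij) == 1L) return(1)
    stop("degenerate confusion matrix: zero normalization but partitions differ")
  }
  num / den
}

#' Export the module co-structure bipartite graph
#'
#' Builds the module-level bipartite graph linking each module of the
#' first partition to each module of the second with which it shares
#' species; edge weight = number of shared species (link thickness in the
#' usual rendering). Module nodes carry their size and a flag marking
#' modules whose members all have zero degree in the corresponding layer
#' (when layers are supplied) — the fate of species interacting in only
#' one layer.
#'
#' @param partition_h,partition_v aligned `network_partition` objects.
#' @param path base output path: `<path>.graphml` and `<path>.tsv`
#'   (columns module_h, module_v, shared_species) are written.
#' @param layer_h,layer_v optional `bipartite_layer`s used to flag
#'   zero-degree-only modules.
#' @return The igraph module graph, invisibly.
#' @export
costructure_graph <- function(partition_h, partition_v, path,
                              layer_h = NULL, layer_v = NULL) {
  conf <- confusion(partition_h, partition_v)
  n_ij <- conf$n_ij
  edges <- which(n_ij > 0, arr.ind = TRUE)
  df <- data.frame(
    module_h = paste0("H", rownames(n_ij)[edges[, 1L]]),
    module_v = paste0("V", colnames(n_ij)[edges[, 2L]]),
    shared_species = n_ij[edges],
    stringsAsFactors = FALSE)
  df <- df[order(df$module_h, df$module_v), , drop = FALSE]
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    df, directed = FALSE,
    vertices = data.frame(
      name = c(paste0("H", rownames(n_ij)), paste0("V", colnames(n_ij))),
      layer = rep(c("H", "V"), c(nrow(n_ij), ncol(n_ij))),
      size = c(unname(conf$row_sums), unname(conf$col_sums)),
      only_zero_degree = c(
        module_zero_flag(partition_h, layer_h),
        module_zero_flag(partition_v, layer_v)),
      stringsAsFactors = FALSE))
  igraph::E(g)$weight <- df$shared_species
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  invisible(g)
}

# TRUE per module when every member has zero degree in the layer
module_zero_flag <- function(partition, layer) {
  memb <- member_vector(partition)
  ids <- sort(unique(memb))
  if (is.null(layer)) return(rep(NA, length(ids)))
  d <- c(degrees(layer, "rows"), degrees(layer, "cols"))[names(memb)]
  vapply(ids, function(i) all(d[memb == i] == 0), NA)
}
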