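#' Construct a bipartite interaction layer
#'
#' A `bipartite_layer` holds one binary bipartite network: an `m x p`
#' incidence matrix whose rows are one guild (e.g. Lepidoptera species) and
#' whose columns are the other guild (e.g. plant species). Entry 1 means the
#' row species interacts with the column species in this layer.
#'
#' Weighted input is binarized at `> 0` with a warning: the method is defined
#' on presence/absence interactions only.
#'
#' @param incidence numeric matrix of 0/1 entries (values `> 0` are binarized
#'   with a warning). Row and column names are used as species labels when
#'   `rows`/`cols` are not given.
#' @param name text label of the layer (e.g. `"herbivory"`).
#' @param rows,cols optional character vectors of species labels; must be
#'   unique and must not overlap each other (a species cannot belong to both
#'   guilds of a bipartite graph).
#' @return An object of class `bipartite_layer`: a list with elements
#'   `name`, `rows`, `cols` and the binary `incidence` matrix (dimnames set).
#' @examples
#' b <- bipartite_layer(matrix(c(1, 0, 1, 1), 2, 2,
#'   dimnames = list(c("lep1", "lep2"), c("pl1", "pl2"))), name = "herbivory")
#' layer_summary(b)
#' @export
bipartite_layer <- function(incidence, name = "layer", rows = NULL, cols = NULL) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  if (nrow(incidence) < 1L || ncol(incidence) < 1L)
    stop("incidence matrix must have at least one row and one column")
  if (any(is.na(incidence)) || !is.numeric(incidence))
    stop("incidence matrix must be numeric with no missing values")
  if (any(incidence < 0)) stop("incidence entries must be non-negative")
  if (any(incidence != 0 & incidence != 1)) {
    warning("non-binary incidence entries binarized at > 0")
    incidence <- (incidence > 0) + 0
  }
  if (is.null(rows)) rows <- rownames(incidence)
  if (is.null(cols)) cols <- colnames(incidence)
  if (is.null(rows)) rows <- paste0("r", seq_len(nrow(incidence)))
  if (is.null(cols)) cols <- paste0("c", seq_len(ncol(incidence)))
  rows <- as.character(rows); cols <- as.character(cols)
  if (length(rows) != nrow(incidence) || length(cols) != ncol(incidence))
    stop("label lengths do not match incidence dimensions")
  if (anyDuplicated(rows)) stop("duplicate row labels: ",
                                paste(unique(rows[duplicated(rows)]), collapse = ", "))
  if (anyDuplicated(cols)) stop("duplicate column labels: ",
                                paste(unique(cols[duplicated(cols)]), collapse = ", "))
  both <- intersect(rows, cols)
  if (length(both))
    stop("bipartite violation: labels in both guilds: ",
         paste(both, collapse = ", "))
  storage.mode(incidence) <- "double"
  dimnames(incidence) <- list(rows, cols)
  structure(list(name = as.character(name)[1], rows = rows, cols = cols,
                 incidence = incidence),
            class = "bipartite_layer")
}

#' @export
print.bipartite_layer <- function(x, ...) {
  s <- layer_summary(x)
  cat(sprintf("bipartite_layer '%s': %d x %d species, L = %d, C = %.4g\n",
              x$name, s$n_rows, s$n_cols, s$n_links, s$connectance))
  invisible(x)
}

#' Pair two bipartite layers over identical species sets
#'
#' The two layers of a multilayer pair must describe the same row guild and
#' the same column guild, in the same order. Species recorded in only one
#' layer are aligned into both by zero-padding (an all-zero row or column in
#' the layer where they have no interactions), so that zero-degree species
#' stay in the analysis: the degree co-distribution and the module
#' composition comparison both count them.
#'
#' @param layer1,layer2 `bipartite_layer` objects.
#' @param align if `TRUE` (default), take the union of row labels and of
#'   column labels, sort each lexicographically (`"C"` collation for
#'   reproducibility) and zero-pad each layer to the union. If `FALSE`, the
#'   labels must already match exactly.
#' @return An object of class `multilayer_pair`: list with `layer1`,
#'   `layer2`, aligned and ordered identically.
#' @examples
#' h <- bipartite_layer(matrix(1, 1, 1, dimnames = list("lep1", "pl1")), "herbivory")
#' v <- bipartite_layer(matrix(1, 1, 1, dimnames = list("lep2", "pl1")), "visitation")
#' p <- multilayer_pair(h, v)   # lep1, lep2 present in both layers
#' p$layer1$rows
#' @export
multilayer_pair <- function(layer1, layer2, align = TRUE) {
  stopifnot(inherits(layer1, "bipartite_layer"), inherits(layer2, "bipartite_layer"))
  if (align) {
    rows <- sort_labels(union(layer1$rows, layer2$rows))
    cols <- sort_labels(union(layer1$cols, layer2$cols))
    bad <- intersect(rows, cols)
    if (length(bad))
      stop("bipartite violation across layers: labels in both guilds: ",
           paste(bad, collapse = ", "))
    layer1 <- pad_layer(layer1, rows, cols)
    layer2 <- pad_layer(layer2, rows, cols)
  } else {
    if (!identical(layer1$rows, layer2$rows) || !identical(layer1$cols, layer2$cols))
      stop("layers are not aligned; use align = TRUE")
  }
  structure(list(layer1 = layer1, layer2 = layer2), class = "multilayer_pair")
}

# lexicographic order independent of locale
sort_labels <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

# zero-pad a layer to given row/col universes, preserving existing entries
pad_layer <- function(layer, rows, cols) {
  inc <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  inc[layer$rows, layer$cols] <- layer$incidence
  bipartite_layer(inc, name = layer$name)
}

#' @export
print.multilayer_pair <- function(x, ...) {
  cat(sprintf("multilayer_pair: %d row species x %d column species\n",
              length(x$layer1$rows), length(x$layer1$cols)))
  print(x$layer1); print(x$layer2)
  invisible(x)
}

#' Summary descriptors of one layer
#'
#' Computes the link count `L`, the connectance `C = L / (m * p)` (the
#' realized fraction of possible interactions between `m` row species and
#' `p` column species), and the number of zero-degree species in each guild.
#'
#' @param layer a `bipartite_layer`.
#' @return A list of class `layer_summary` with fields `name`, `n_rows`,
#'   `n_cols`, `n_links`, `connectance`, `n_zero_degree_rows`,
#'   `n_zero_degree_cols`. Connectance is returned at full precision;
#'   round only for presentation.
#' @export
layer_summary <- function(layer) {
  stopifnot(inherits(layer, "bipartite_layer"))
  L <- sum(layer$incidence)
  structure(list(
    name = layer$name,
    n_rows = nrow(layer$incidence),
    n_cols = ncol(layer$incidence),
    n_links = as.integer(L),
    connectance = L / (nrow(layer$incidence) * ncol(layer$incidence)),
    n_zero_degree_rows = sum(rowSums(layer$incidence) == 0),
    n_zero_degree_cols = sum(colSums(layer$incidence) == 0)
  ), class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  cat(sprintf(
    "layer '%s': %d x %d, L = %d, C = %.6g, zero-degree rows = %d, cols = %d\n",
    x$name, x$n_rows, x$n_cols, x$n_links, x$connectance,
    x$n_zero_degree_rows, x$n_zero_degree_cols))
  invisible(x)
}

# symmetric (m+p) x (m+p) adjacency of one layer:
#   [ 0   B ]
#   [ B'  0 ]
# with the m row-guild species first, then the p column-guild species.
layer_adjacency <- function(layer) {
  B <- layer$incidence
  m <- nrow(B); p <- ncol(B)
  A <- matrix(0, m + p, m + p)
  A[seq_len(m), m + seq_len(p)] <- B
  A[m + seq_len(p), seq_len(m)] <- t(B)
  dimnames(A) <- list(c(layer$rows, layer$cols), c(layer$rows, layer$cols))
  A
}

#' Full three-block adjacency matrix of a multilayer pair
#'
#' Assembles the symmetric `(m + p + m) x (m + p + m)` adjacency matrix of
#' the complete two-layer system, with nodes ordered as (row guild in layer
#' 1, shared column guild, row guild in layer 2). For a Lepidoptera-plant
#' system this is (adults, plants, larvae): the layer-1 incidence `B` and the
#' layer-2 incidence `C` sit in the off-diagonal blocks
#' \deqn{A = \begin{pmatrix} 0 & B & 0 \\ B^T & 0 & C^T \\ 0 & C & 0 \end{pmatrix}}
#' and every other block is zero. Row-guild species appear twice (once per
#' layer); their node labels are suffixed with `|<layer name>` so that all
#' labels stay unique.
#'
#' @param pair a `multilayer_pair`.
#' @return Symmetric binary matrix with informative dimnames.
#' @export
full_adjacency <- function(pair) {
  stopifnot(inherits(pair, "multilayer_pair"))
  B <- pair$layer1$incidence
  C <- pair$layer2$incidence
  m <- nrow(B); p <- ncol(B)
  A <- matrix(0, 2 * m + p, 2 * m + p)
  i1 <- seq_len(m); ip <- m + seq_len(p); i2 <- m + p + seq_len(m)
  A[i1, ip] <- B
  A[ip, i1] <- t(B)
  A[ip, i2] <- t(C)
  A[i2, ip] <- C
  labs <- c(paste(pair$layer1$rows, pair$layer1$name, sep = "|"),
            pair$layer1$cols,
            paste(pair$layer2$rows, pair$layer2$name, sep = "|"))
  dimnames(A) <- list(labs, labs)
  A
}
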