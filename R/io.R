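#' Read a two-layer edge list
#'
#' Reads a long-format interaction table with at least three columns:
#' `species_a` (row guild), `species_b` (column guild) and `layer`. An
#' optional `weight` column is binarized at `> 0` with a warning (the method
#' is presence/absence). Lines starting with `#` and blank lines are
#' skipped; duplicate edges collapse to a single interaction. The row and
#' column universes of the returned pair are the unions of the species seen
#' in either layer, sorted lexicographically, with zero-padding where a
#' species has no interactions in one layer.
#'
#' @param path path to a delimited text file. If the file's first
#'   non-comment line contains the column names they are honoured;
#'   otherwise columns are taken positionally as (species_a, species_b,
#'   layer\[, weight\]).
#' @param layer_names character vector of length 2 naming the two layers in
#'   the order (layer1, layer2); every `layer` value in the file must be one
#'   of these.
#' @param sep field delimiter; default `NULL` chooses `","` for `.csv`
#'   files and tab otherwise.
#' @param normalize_labels if `TRUE`, species labels are lower-cased and
#'   stripped of surrounding whitespace before matching. Default `FALSE`:
#'   label matching is exact and case-sensitive.
#' @return A [multilayer_pair()].
#' @seealso [read_incidence()], [write_edge_list()]
#' @export
read_edge_list <- function(path, layer_names = c("layer1", "layer2"),
                           sep = NULL, normalize_labels = FALSE) {
  stopifnot(length(layer_names) == 2L, !anyDuplicated(layer_names))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop("no data lines in ", path)
  lineno <- which(keep)
  fields <- strsplit(raw[keep], sep, fixed = TRUE)
  fields <- lapply(fields, trimws)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L)
    stop("edge list needs >= 3 columns (species_a, species_b, layer); line ",
         lineno[which.min(lengths(fields))], " has ", ncol_min)
  header <- fields[[1L]]
  named <- all(c("species_a", "species_b", "layer") %in% header)
  if (named) {
    ia <- match("species_a", header); ib <- match("species_b", header)
    il <- match("layer", header);     iw <- match("weight", header)
    fields <- fields[-1L]; lineno <- lineno[-1L]
  } else {
    ia <- 1L; ib <- 2L; il <- 3L
    iw <- if (min(lengths(fields)) >= 4L) 4L else NA_integer_
  }
  if (!length(fields)) stop("no edges in ", path)
  a <- vapply(fields, `[[`, "", ia)
  b <- vapply(fields, `[[`, "", ib)
  lay <- vapply(fields, `[[`, "", il)
  if (normalize_labels) { a <- tolower(trimws(a)); b <- tolower(trimws(b)) }
  bad <- !(lay %in% layer_names)
  if (any(bad))
    stop("unknown layer label '", lay[which(bad)[1L]], "' at line ",
         lineno[which(bad)[1L]], " (expected one of: ",
         paste(layer_names, collapse = ", "), ")")
  if (!is.na(iw)) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", iw)))
    if (anyNA(w)) stop("non-numeric weight at line ", lineno[which(is.na(w))[1L]])
    if (any(w != 0 & w != 1))
      warning("weight column binarized at > 0; quantitative strengths are ignored")
    drop <- w <= 0
    a <- a[!drop]; b <- b[!drop]; lay <- lay[!drop]
  }
  both <- intersect(a, b)
  if (length(both))
    stop("bipartite violation: species in both guilds: ",
         paste(unique(both), collapse = ", "))
  rows <- sort_labels(unique(a)); cols <- sort_labels(unique(b))
  make_layer <- function(nm) {
    inc <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    sel <- lay == nm
    inc[cbind(match(a[sel], rows), match(b[sel], cols))] <- 1
    bipartite_layer(inc, name = nm)
  }
  multilayer_pair(make_layer(layer_names[1L]), make_layer(layer_names[2L]),
                  align = FALSE)
}

#' Read two labelled incidence matrices as a multilayer pair
#'
#' Each file holds one layer as a labelled matrix: first row = column
#' species labels, first column = row species labels, cells strictly 0 or 1
#' (any other value is an error — binarize upstream if your data are
#' quantitative). Species present in only one file are zero-padded into the
#' other layer; label sets are unioned, never dropped.
#'
#' @param path1,path2 paths to the layer-1 and layer-2 matrix files
#'   (CSV or TSV; delimiter chosen per file as in [read_edge_list()]).
#' @param layer_names labels for the two layers.
#' @inheritParams read_edge_list
#' @return A [multilayer_pair()].
#' @export
read_incidence <- function(path1, path2, layer_names = c("layer1", "layer2"),
                           sep = NULL, normalize_labels = FALSE) {
  read_one <- function(path, nm) {
    s <- if (is.null(sep)) {
      if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    } else sep
    x <- utils::read.table(path, header = TRUE, sep = s, row.names = 1L,
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    x <- as.matrix(x)
    if (!is.numeric(x)) stop("non-numeric cell in ", path)
    if (any(is.na(x)) || any(!(x %in% c(0, 1))))
      stop("incidence cells must be 0 or 1 in ", path)
    if (normalize_labels) {
      rownames(x) <- tolower(trimws(rownames(x)))
      colnames(x) <- tolower(trimws(colnames(x)))
    }
    bipartite_layer(x, name = nm)
  }
  multilayer_pair(read_one(path1, layer_names[1L]),
                  read_one(path2, layer_names[2L]))
}

#' Write a multilayer pair as a long-format edge list
#'
#' Writes one line per interaction with header `species_a`, `species_b`,
#' `layer`; layer 1 first, then layer 2, rows in the pair's label order.
#' Re-reading the file with [read_edge_list()] reproduces the pair exactly
#' (zero-degree species excepted: a species with no interactions in either
#' layer has no edge to carry it).
#'
#' @param pair a `multilayer_pair`.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(pair, path, sep = "\t") {
  stopifnot(inherits(pair, "multilayer_pair"))
  one <- function(layer) {
    idx <- which(layer$incidence == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    data.frame(species_a = layer$rows[idx[, 1L]],
               species_b = layer$cols[idx[, 2L]],
               layer = layer$name, stringsAsFactors = FALSE)
  }
  df <- rbind(one(pair$layer1), one(pair$layer2))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a layer or the full two-layer system as GraphML
#'
#' Writes an undirected graph for external visualization. For a
#' `bipartite_layer`, nodes carry a logical `is_row_guild` attribute. For a
#' `multilayer_pair`, the full three-block adjacency (row guild of layer 1,
#' shared column guild, row guild of layer 2) is exported, so row-guild
#' species appear once per layer with `|<layer>`-suffixed names.
#'
#' @param x a `bipartite_layer` or `multilayer_pair`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  if (inherits(x, "bipartite_layer")) {
    g <- igraph::graph_from_biadjacency_matrix(x$incidence)
    igraph::V(g)$is_row_guild <- igraph::V(g)$type == FALSE
  } else if (inherits(x, "multilayer_pair")) {
    g <- igraph::graph_from_adjacency_matrix(full_adjacency(x),
                                             mode = "undirected")
  } else stop("cannot export object of class ", paste(class(x), collapse = "/"))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
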