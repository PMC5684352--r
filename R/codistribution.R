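#' Species degrees in one layer
#'
#' The degree of a species is its number of interaction partners in a
#' layer: the row (or column) sum of the incidence matrix. Zero-degree
#' species are included — species with no interactions in a layer are part
#' of the method, not missing data.
#'
#' @param layer a `bipartite_layer`.
#' @param guild `"rows"` or `"cols"`: which guild to compute degrees for.
#' @return Named integer vector, one entry per species of the guild.
#' @export
degrees <- function(layer, guild = c("rows", "cols")) {
  stopifnot(inherits(layer, "bipartite_layer"))
  guild <- match.arg(guild)
  d <- if (guild == "rows") rowSums(layer$incidence) else colSums(layer$incidence)
  storage.mode(d) <- "integer"
  d
}

#' Paired-degree contingency table of a multilayer pair
#'
#' Tabulates, for one guild, how many species have degree `u` in layer 1
#' and degree `w` in layer 2: the contingency table `K[u, w]` of the degree
#' co-distribution. Degree levels are the raw observed integers (no
#' binning); only levels attained by at least one species appear, so the
#' table has no all-zero row or column margin. Species with degree 0 in
#' both layers are counted — the (0, 0) cell is a real interaction class.
#'
#' @param pair a `multilayer_pair`.
#' @param guild `"rows"` or `"cols"`: the guild whose degrees are paired.
#' @return An object of class `degree_cotable`: list with `guild`,
#'   `u_levels`, `w_levels` (sorted distinct degrees in layers 1 and 2),
#'   the `counts` matrix, total `n`, and the two layer names.
#' @seealso [independence_test()], [mosaic_export()]
#' @export
co_table <- function(pair, guild = c("rows", "cols")) {
  stopifnot(inherits(pair, "multilayer_pair"))
  guild <- match.arg(guild)
  u <- degrees(pair$layer1, guild)
  w <- degrees(pair$layer2, guild)
  u_levels <- sort(unique(u))
  w_levels <- sort(unique(w))
  counts <- table(factor(u, levels = u_levels), factor(w, levels = w_levels))
  counts <- matrix(as.integer(counts), length(u_levels), length(w_levels),
                   dimnames = list(u = u_levels, w = w_levels))
  structure(list(guild = guild, u_levels = u_levels, w_levels = w_levels,
                 counts = counts, n = length(u),
                 layer_names = c(pair$layer1$name, pair$layer2$name)),
            class = "degree_cotable")
}

#' @export
print.degree_cotable <- function(x, ...) {
  cat(sprintf("degree co-distribution (%s guild): %d species, %d x %d degree levels\n",
              x$guild, x$n, length(x$u_levels), length(x$w_levels)))
  invisible(x)
}

#' Chi-squared test of degree-co-distribution independence
#'
#' Tests whether a species' degree in one layer is independent of its
#' degree in the other. Under independence the expected count in cell
#' `(u, w)` is `n * p_u * p_w`, where `p_u` and `p_w` are the marginal
#' degree frequencies of the two layers; the Pearson statistic is
#' `sum((K - E)^2 / E)` on `(|u| - 1)(|w| - 1)` degrees of freedom.
#' Per-cell Pearson residuals `(K - E) / sqrt(E)` localise which degree
#' combinations are over- (positive) or under- (negative) represented.
#'
#' Degree tables are typically sparse (many expected counts below 5); the
#' asymptotic chi-squared reference is then approximate and a warning is
#' issued. `p_method = "simulate"` draws tables with the observed margins
#' (via [stats::r2dtable()]) for a seeded Monte-Carlo p-value of
#' `(1 + #(chi2_sim >= chi2_obs)) / (n_sim + 1)`.
#'
#' @param table a `degree_cotable` from [co_table()].
#' @param p_method `"asymptotic"` (default, the conventional report) or
#'   `"simulate"` for the fixed-margin Monte-Carlo p-value.
#' @param n_sim number of Monte-Carlo tables when simulating.
#' @param seed integer seed for the Monte-Carlo draw (required when
#'   simulating, so results are reproducible).
#' @return Object of class `codistribution_result`: the input `table` plus
#'   `expected`, `chi2`, `df`, `p_value`, `p_method`, `residuals` and the
#'   per-cell `shading` codes (see [mosaic_export()]).
#' @examples
#' pr <- planted_pair(n_rows = 20, n_cols = 20, seed = 1)
#' tab <- co_table(pr$pair, "cols")
#' independence_test(tab, p_method = "simulate", n_sim = 199, seed = 1)
#' @export
independence_test <- function(table, p_method = c("asymptotic", "simulate"),
                              n_sim = 1999, seed = NULL) {
  stopifnot(inherits(table, "degree_cotable"))
  p_method <- match.arg(p_method)
  K <- table$counts
  n <- table$n
  if (n < 1L) stop("empty table")
  rs <- rowSums(K); cs <- colSums(K)
  E <- outer(rs, cs) / n
  chi2 <- sum((K - E)^2 / E)
  df <- (nrow(K) - 1L) * (ncol(K) - 1L)
  resid <- (K - E) / sqrt(E)
  if (p_method == "asymptotic") {
    if (nrow(K) < 2L || ncol(K) < 2L)
      stop("degenerate table (a single degree level on one side); ",
           "use p_method = \"simulate\"")
    if (mean(E < 5) > 0.2)
      warning("more than 20% of expected counts are below 5; ",
              "the asymptotic p-value is approximate - consider ",
              "p_method = \"simulate\"")
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    if (is.null(seed)) stop("p_method = \"simulate\" requires a seed")
    if (nrow(K) < 2L || ncol(K) < 2L) {
      # the margins fully determine a 1 x k table: the null is a point mass
      p <- 1
    } else {
      local_seed(seed)
      sims <- stats::r2dtable(n_sim, rs, cs)
      chi2_sim <- vapply(sims, function(s) sum((s - E)^2 / E), 0)
      p <- (1 + sum(chi2_sim >= chi2 - 1e-12)) / (n_sim + 1)
    }
  }
  structure(list(table = table, expected = E, chi2 = chi2, df = df,
                 p_value = p, p_method = p_method,
                 n_sim = if (p_method == "simulate") n_sim else NA_integer_,
                 residuals = resid,
                 shading = residual_shading(resid)),
            class = "codistribution_result")
}

# run code under a temporary RNG state restored on exit
local_seed <- function(seed, envir = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  withr::defer({
    if (has_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, envir = envir)
  set.seed(seed)
  invisible(NULL)
}

#' Shading codes for Pearson residuals
#'
#' Maps residual magnitude to the five-level shading convention of
#' residual-based mosaic displays: `|r| >= 4` is "strong" (significant at
#' approximately alpha = 0.0001), `2 <= |r| < 4` is moderate
#' (approximately alpha = 0.05), `|r| < 2` is neutral; the sign marks
#' over- vs under-representation.
#'
#' @param r numeric vector or matrix of Pearson residuals.
#' @return Character object of the same shape with values in
#'   `strong-positive`, `positive`, `neutral`, `negative`,
#'   `strong-negative`.
#' @export
residual_shading <- function(r) {
  out <- ifelse(abs(r) >= 4, ifelse(r > 0, "strong-positive", "strong-negative"),
         ifelse(abs(r) >= 2, ifelse(r > 0, "positive", "negative"), "neutral"))
  if (is.matrix(r)) dimnames(out) <- dimnames(r)
  out
}

#' Export a mosaic table of the degree co-distribution
#'
#' Writes the long-format table behind a residual-shaded mosaic plot: one
#' row per cell of the degree contingency table with the observed count,
#' the expected count under independence, the Pearson residual, the
#' shading code of [residual_shading()], and a `zero_count` flag marking
#' cells observed exactly zero times (drawn as a small bullet in mosaic
#' displays, to distinguish structural absence from small frequency).
#'
#' @param result a `codistribution_result` from [independence_test()].
#' @param path output TSV path.
#' @return The exported `data.frame`, invisibly.
#' @seealso [plot.codistribution_result()] for a quick rendering.
#' @export
mosaic_export <- function(result, path) {
  stopifnot(inherits(result, "codistribution_result"))
  tab <- result$table
  grid <- expand.grid(w = seq_along(tab$w_levels), u = seq_along(tab$u_levels))
  df <- data.frame(
    u = tab$u_levels[grid$u],
    w = tab$w_levels[grid$w],
    count = result$table$counts[cbind(grid$u, grid$w)],
    expected = result$expected[cbind(grid$u, grid$w)],
    residual = result$residuals[cbind(grid$u, grid$w)],
    shading = result$shading[cbind(grid$u, grid$w)],
    stringsAsFactors = FALSE)
  df <- df[order(df$u, df$w), c("u", "w", "count", "expected", "residual", "shading")]
  df$zero_count <- df$count == 0L
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @export
print.codistribution_result <- function(x, ...) {
  cat(sprintf("degree co-distribution independence test (%s guild)\n", x$table$guild))
  cat(sprintf("  chi2 = %.4g, df = %d, p %s %.4g (%s)\n",
              x$chi2, x$df,
              if (x$p_value < 2.2e-16 && x$p_method == "asymptotic") "<" else "=",
              max(x$p_value, 2.2e-16), x$p_method))
  cat(sprintf("  residual range: [%.2f, %.2f]\n",
              min(x$residuals), max(x$residuals)))
  invisible(x)
}

#' Mosaic rendering of a degree co-distribution result
#'
#' Draws a base-graphics mosaic of the degree contingency table, shaded by
#' Pearson residual via [graphics::mosaicplot()]'s standard shading. For
#' publication-grade mosaics use the exported table of [mosaic_export()]
#' with a dedicated plotting tool.
#'
#' @param x a `codistribution_result`.
#' @param ... passed to [graphics::mosaicplot()].
#' @return `x`, invisibly.
#' @export
plot.codistribution_result <- function(x, ...) {
  tab <- x$table$counts
  names(dimnames(tab)) <- paste("degree in", x$table$layer_names)
  graphics::mosaicplot(tab, shade = TRUE,
                       main = sprintf("degree co-distribution (%s)", x$table$guild),
                       ...)
  invisible(x)
}
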