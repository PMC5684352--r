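#' Permutation test of module-composition similarity
#'
#' The headline co-structure test: is the normalized mutual information
#' between the module classifications of the two layers larger (or
#' smaller) than expected for networks with exactly the observed degree
#' sequences? The observed NMI is computed once from [detect_modules()] on
#' each layer. For each replicate, both layers are independently
#' curveball-randomized (degree sequences preserved exactly, asserted
#' in-line), modules are re-detected with the same settings, and the NMI
#' recomputed on the full species set. Empirical p-values use the add-one
#' permutation correction `(1 + #extreme) / (n_replicates + 1)`; ties
#' count as extreme in both tails, so `p_ge` asks whether the observed
#' similarity is *higher* than random, `p_le` whether it is lower, and
#' `p_two = min(1, 2 min(p_ge, p_le))`.
#'
#' @param pair a [multilayer_pair()].
#' @param n_replicates number of null replicates (default 999).
#' @param n_trades curveball trades per randomization; default
#'   `5 * max(m, p)` per layer (see [curveball_randomize()]).
#' @param seed integer seed; each replicate derives its own stream from
#'   it, so runs are reproducible end to end.
#' @param tol,fine_tune passed to [detect_modules()] for both the observed
#'   and every replicate detection.
#' @param restrict_interacting if `TRUE`, the NMI (observed and null) is
#'   computed only over species with at least one interaction in *both*
#'   layers — a sensitivity analysis; the default `FALSE` keeps the full
#'   species set including zero-degree species, whose singleton modules
#'   are part of the classification being compared.
#' @return Object of class `nmi_null`: `i_observed`, vector `i_null`,
#'   `n_replicates`, the five-number summary of `i_null` (`min`, `q1`,
#'   `median`, `q3`, `max`), `p_ge`, `p_le`, `p_two`, `seed`, `n_trades`,
#'   plus the two observed partitions.
#' @examples
#' pp <- planted_pair(n_rows = 20, n_cols = 20, k_modules = 2, seed = 3)
#' nmi_null_test(pp$pair, n_replicates = 19, seed = 3)
#' @export
nmi_null_test <- function(pair, n_replicates = 999, n_trades = NULL, seed,
                          tol = 1e-10, fine_tune = TRUE,
                          restrict_interacting = FALSE) {
  stopifnot(inherits(pair, "multilayer_pair"))
  if (missing(seed)) stop("nmi_null_test requires a seed")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  part1 <- detect_modules(pair$layer1, tol = tol, fine_tune = fine_tune)
  part2 <- detect_modules(pair$layer2, tol = tol, fine_tune = fine_tune)
  keep <- if (restrict_interacting) interacting_species(pair) else NULL
  i_obs <- nmi_restricted(part1, part2, keep)

  local_seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 2L * n_replicates),
                      ncol = 2L)
  rs1 <- rowSums(pair$layer1$incidence); cs1 <- colSums(pair$layer1$incidence)
  rs2 <- rowSums(pair$layer2$incidence); cs2 <- colSums(pair$layer2$incidence)
  i_null <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    l1 <- curveball_randomize(pair$layer1, n_trades, seed = rep_seeds[r, 1L])
    l2 <- curveball_randomize(pair$layer2, n_trades, seed = rep_seeds[r, 2L])
    stopifnot(all(rowSums(l1$incidence) == rs1), all(colSums(l1$incidence) == cs1),
              all(rowSums(l2$incidence) == rs2), all(colSums(l2$incidence) == cs2))
    p1 <- detect_modules(l1, tol = tol, fine_tune = fine_tune)
    p2 <- detect_modules(l2, tol = tol, fine_tune = fine_tune)
    i_null[r] <- nmi_restricted(p1, p2, keep)
  }
  q <- unname(stats::quantile(i_null, c(0, 0.25, 0.5, 0.75, 1)))
  p_ge <- (1 + sum(i_null >= i_obs - 1e-12)) / (n_replicates + 1)
  p_le <- (1 + sum(i_null <= i_obs + 1e-12)) / (n_replicates + 1)
  structure(list(i_observed = i_obs, i_null = i_null,
                 n_replicates = n_replicates,
                 min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L],
                 p_ge = p_ge, p_le = p_le, p_two = min(1, 2 * min(p_ge, p_le)),
                 seed = seed,
                 n_trades = if (is.null(n_trades)) "auto (5 x max(m, p))" else n_trades,
                 restrict_interacting = restrict_interacting,
                 partition1 = part1, partition2 = part2),
            class = "nmi_null")
}

# labels of species with degree >= 1 in both layers (either guild)
interacting_species <- function(pair) {
  d1 <- c(degrees(pair$layer1, "rows"), degrees(pair$layer1, "cols"))
  d2 <- c(degrees(pair$layer2, "rows"), degrees(pair$layer2, "cols"))
  names(d1)[d1 > 0 & d2[names(d1)] > 0]
}

nmi_restricted <- function(part1, part2, keep = NULL) {
  m1 <- part1$membership; m2 <- part2$membership
  if (!is.null(keep)) {
    if (!length(keep)) stop("no species interact in both layers")
    m1 <- m1[keep]; m2 <- m2[keep]
  }
  nmi(confusion(m1, m2))
}

#' @export
print.nmi_null <- function(x, ...) {
  cat("module-composition similarity vs degree-preserving null\n")
  cat(sprintf("  observed I = %.4g  (null over %d replicates)\n",
              x$i_observed, x$n_replicates))
  cat(sprintf("  null range [%.3g, %.3g], quartiles [%.3g, %.3g], median %.3g\n",
              x$min, x$max, x$q1, x$q3, x$median))
  cat(sprintf("  p_ge = %.4g (higher than random?), p_le = %.4g, p_two = %.4g\n",
              x$p_ge, x$p_le, x$p_two))
  invisible(x)
}

#' Run the full co-structure analysis and write a report bundle
#'
#' End-to-end driver: load and align the pair, summarize each layer,
#' analyse the degree co-distribution of both guilds (with mosaic-table
#' exports), detect modules in each layer, export the module co-structure
#' graph, and run the NMI permutation test against the degree-preserving
#' null. Everything randomized derives from `config$seed`, so two runs
#' with the same configuration produce byte-identical `report.json`.
#'
#' @param config a named list with entries:
#' \describe{
#'   \item{`edges`}{path to a two-layer edge list, *or*}
#'   \item{`incidence`}{character vector of two incidence-matrix paths, *or*}
#'   \item{`pair`}{an in-memory [multilayer_pair()];}
#'   \item{`layer_names`}{labels of the two layers (default
#'     `c("layer1", "layer2")`);}
#'   \item{`outdir`}{output directory (created if missing);}
#'   \item{`seed`}{integer seed (required);}
#'   \item{`n_replicates`}{null replicates (default 999, must be >= 1);}
#'   \item{`n_trades`}{curveball trades (default auto);}
#'   \item{`p_method`, `n_sim`}{chi-squared p-value method per
#'     [independence_test()] (default asymptotic);}
#'   \item{`tol`, `fine_tune`, `restrict_interacting`}{module/NMI options;}
#'   \item{`normalize_labels`, `sep`}{reader options;}
#'   \item{`mosaic_png`}{also render PNG mosaics (default `FALSE`).}
#' }
#' @return The report, invisibly (a nested list mirroring `report.json`).
#'   Side effects in `outdir`: `report.json`, `degrees_<guild>.tsv`,
#'   `mosaic_<guild>.tsv`, `modules_<layer>.tsv`, `module_graph.graphml`
#'   and `.tsv`, `null_i.tsv`, and `log.txt` recording seeds and options.
#' @export
run_full_analysis <- function(config) {
  cfg <- validate_config(config)
  pair <- if (!is.null(cfg$pair)) cfg$pair
    else if (!is.null(cfg$edges))
      read_edge_list(cfg$edges, cfg$layer_names, sep = cfg$sep,
                     normalize_labels = cfg$normalize_labels)
    else read_incidence(cfg$incidence[1L], cfg$incidence[2L], cfg$layer_names,
                        sep = cfg$sep, normalize_labels = cfg$normalize_labels)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$outdir, ...)

  summaries <- list(layer1 = unclass(layer_summary(pair$layer1)),
                    layer2 = unclass(layer_summary(pair$layer2)))

  codist <- list()
  for (guild in c("rows", "cols")) {
    tab <- co_table(pair, guild)
    res <- independence_test(tab, p_method = cfg$p_method, n_sim = cfg$n_sim,
                             seed = cfg$seed + (guild == "cols"))
    d1 <- degrees(pair$layer1, guild); d2 <- degrees(pair$layer2, guild)
    utils::write.table(
      data.frame(species = names(d1), degree_layer1 = unname(d1),
                 degree_layer2 = unname(d2), stringsAsFactors = FALSE),
      out(sprintf("degrees_%s.tsv", guild)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    mosaic_export(res, out(sprintf("mosaic_%s.tsv", guild)))
    if (isTRUE(cfg$mosaic_png)) {
      grDevices::png(out(sprintf("mosaic_%s.png", guild)), 900, 900)
      plot(res)
      grDevices::dev.off()
    }
    codist[[guild]] <- list(chi2 = res$chi2, df = res$df,
                            p_value = res$p_value, p_method = res$p_method,
                            max_residual = max(res$residuals),
                            min_residual = min(res$residuals))
  }

  null_res <- nmi_null_test(pair, n_replicates = cfg$n_replicates,
                            n_trades = cfg$n_trades, seed = cfg$seed,
                            tol = cfg$tol, fine_tune = cfg$fine_tune,
                            restrict_interacting = cfg$restrict_interacting)
  part1 <- null_res$partition1; part2 <- null_res$partition2
  write_partition(part1, out(sprintf("modules_%s.tsv", pair$layer1$name)))
  write_partition(part2, out(sprintf("modules_%s.tsv", pair$layer2$name)))
  costructure_graph(part1, part2, out("module_graph"),
                    layer_h = pair$layer1, layer_v = pair$layer2)
  utils::write.table(
    data.frame(replicate = seq_along(null_res$i_null), i = null_res$i_null),
    out("null_i.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  module_block <- function(part, layer) {
    ids <- sort(unique(part$membership))
    sizes <- vapply(ids, function(i) sum(part$membership == i), 0L)
    list(n_modules = part$n_modules,
         modularity_q = part$modularity_q,
         n_singleton = sum(sizes == 1L),
         n_multi_species = sum(sizes > 1L),
         n_zero_degree_singletons = sum(module_zero_flag(part, layer) &
                                          sizes == 1L))
  }
  report <- list(
    # outdir is where the report lives, not part of the analysis; keeping it
    # out makes reports byte-comparable across output locations
    parameters = cfg[setdiff(names(cfg), c("pair", "outdir"))],
    layers = summaries,
    degree_codistribution = codist,
    modules = list(layer1 = module_block(part1, pair$layer1),
                   layer2 = module_block(part2, pair$layer2)),
    module_similarity = list(
      i_observed = null_res$i_observed,
      n_replicates = null_res$n_replicates,
      null_min = null_res$min, null_q1 = null_res$q1,
      null_median = null_res$median, null_q3 = null_res$q3,
      null_max = null_res$max,
      p_ge = null_res$p_ge, p_le = null_res$p_le, p_two = null_res$p_two))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c("costructure run log",
               paste0("seed: ", cfg$seed),
               paste0("n_replicates: ", cfg$n_replicates),
               paste0("n_trades: ", if (is.null(cfg$n_trades)) "auto (5 x max(m, p))"
                      else cfg$n_trades),
               paste0("p_method: ", cfg$p_method),
               paste0("tol: ", format(cfg$tol)),
               paste0("fine_tune: ", cfg$fine_tune),
               paste0("restrict_interacting: ", cfg$restrict_interacting)),
             out("log.txt"))
  invisible(report)
}

# validate and default-fill a pipeline configuration; all problems are
# reported together before any computation starts
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a named list")
  defaults <- list(layer_names = c("layer1", "layer2"), sep = NULL,
                   normalize_labels = FALSE, p_method = "asymptotic",
                   n_sim = 1999, n_replicates = 999, n_trades = NULL,
                   tol = 1e-10, fine_tune = TRUE,
                   restrict_interacting = FALSE, mosaic_png = FALSE)
  cfg <- utils::modifyList(defaults, config)
  errs <- character(0)
  sources <- sum(!is.null(cfg$pair), !is.null(cfg$edges), !is.null(cfg$incidence))
  if (sources != 1L)
    errs <- c(errs, "exactly one of 'pair', 'edges' or 'incidence' must be given")
  if (!is.null(cfg$incidence) && length(cfg$incidence) != 2L)
    errs <- c(errs, "'incidence' must give exactly two paths")
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    errs <- c(errs, "an integer 'seed' is required")
  if (is.null(cfg$outdir)) errs <- c(errs, "an 'outdir' is required")
  if (!is.numeric(cfg$n_replicates) || cfg$n_replicates < 1)
    errs <- c(errs, "'n_replicates' must be >= 1")
  if (!cfg$p_method %in% c("asymptotic", "simulate"))
    errs <- c(errs, "'p_method' must be 'asymptotic' or 'simulate'")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
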