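#' Monte-Carlo bias of the estimators across assortment strengths
#'
#' For every assortment level `phi` and every replicate, simulates a fresh
#' trio cohort, fits the three individual-level estimators — per-parent
#' phenotypic OLS ([fitPhenotypicOls()] with `perParent = TRUE`),
#' conventional per-parent MR ([fitStandardMr()]) and the within-family
#' multivariable 2SLS ([fitWfMvmr()]) — and aggregates
#' the per-parent estimates into mean, bias against the configured true
#' dynastic effect, and Monte-Carlo standard error (`SD / sqrt(reps)`).
#' Estimator failures within a replicate are recorded and excluded, never
#' fatal. The whole grid is seeded: replicate `r` at level `phi` uses a seed
#' derived from `seed`, `phi` and `r`.
#'
#' @param baseConfig a [simConfig()] giving the cohort size and phenotype
#'   model; its `assortmentPhi` is overridden by the grid.
#' @param phis assortment levels in `[0, 1]` (default `seq(0, 0.9, 0.1)`).
#' @param reps replicates per level (>= 2).
#' @param seed integer root seed for the grid.
#' @return list of class `"BiasGridResult"` with elements `table`
#'   (one row per phi x estimator x parent: `mean_estimate`, `bias`,
#'   `mc_se`, `n_reps`, `n_failed`), `replicates` (per-replicate estimates),
#'   `true_effect` (named mother/father), and `config` (echo).
#' @seealso [summarizeBias()]
#' @export
runAssortmentGrid <- function(baseConfig, phis = seq(0, 0.9, 0.1),
                              reps = 200, seed = 1) {
  validObject(baseConfig)
  if (reps < 2) stop("reps must be at least 2")
  if (any(phis < 0 | phis > 1)) stop("phis must lie in [0, 1]")
  truth <- c(mother = baseConfig@dynasticMother,
             father = baseConfig@dynasticFather)
  rows <- list()
  fails <- list()
  k <- 0L
  for (phi in phis) {
    for (r in seq_len(reps)) {
      cfg <- baseConfig
      cfg@assortmentPhi <- phi
      cfg@seed <- .stage_seed(seed, sprintf("grid_%.6f_%d", phi, r))
      est <- tryCatch({
        design <- cohortDesign(simulateTrioCohort(cfg))
        rbind(fitPhenotypicOls(design, perParent = TRUE), fitWfMvmr(design),
              fitStandardMr(design))
      }, error = function(e) e)
      if (inherits(est, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          phi = phi, replicate = r, message = conditionMessage(est),
          stringsAsFactors = FALSE)
        next
      }
      k <- k + 1L
      rows[[k]] <- cbind(phi = phi, replicate = r,
                         est[, c("estimator", "exposure", "estimate")])
    }
  }
  replicates <- do.call(rbind, rows)
  if (is.null(replicates)) stop("every replicate failed")
  agg <- do.call(rbind, lapply(
    split(replicates,
          list(replicates$phi, replicates$estimator, replicates$exposure),
          drop = TRUE),
    function(d) {
      data.frame(phi = d$phi[1], estimator = d$estimator[1],
                 parent = d$exposure[1],
                 mean_estimate = mean(d$estimate),
                 bias = mean(d$estimate) - truth[[d$exposure[1]]],
                 mc_se = stats::sd(d$estimate) / sqrt(nrow(d)),
                 n_reps = nrow(d),
                 n_failed = reps - nrow(d),
                 stringsAsFactors = FALSE)
    }))
  agg <- agg[order(agg$phi, agg$estimator, agg$parent), ]
  rownames(agg) <- NULL
  structure(list(table = agg, replicates = replicates, true_effect = truth,
                 config = baseConfig, reps = reps, seed = seed),
            class = "BiasGridResult")
}

#' @export
print.BiasGridResult <- function(x, ...) {
  cat("BiasGridResult:", length(unique(x$table$phi)), "assortment levels x",
      x$reps, "replicates\n")
  print(utils::head(x$table, 12))
  if (nrow(x$table) > 12) cat("...", nrow(x$table) - 12, "more rows\n")
  invisible(x)
}

#' Summarize a bias grid into a table and a figure
#'
#' Recomputes the aggregate table from the stored per-replicate estimates and
#' draws mean estimate against assortment strength per estimator, with
#' 95% Monte-Carlo error bars and a horizontal line at the true effect.
#'
#' @param result a [runAssortmentGrid()] result.
#' @return list with `table` (data.frame) and `plot` (a ggplot object).
#' @export
summarizeBias <- function(result) {
  if (!inherits(result, "BiasGridResult"))
    stop("result must be a BiasGridResult")
  if (!nrow(result$table)) stop("empty bias grid result")
  reps <- result$replicates
  truth <- result$true_effect
  tab <- do.call(rbind, lapply(
    split(reps, list(reps$phi, reps$estimator, reps$exposure), drop = TRUE),
    function(d) data.frame(
      phi = d$phi[1], estimator = d$estimator[1], parent = d$exposure[1],
      mean_estimate = mean(d$estimate),
      bias = mean(d$estimate) - truth[[d$exposure[1]]],
      mc_se = stats::sd(d$estimate) / sqrt(nrow(d)),
      n_reps = nrow(d), stringsAsFactors = FALSE)))
  tab <- tab[order(tab$phi, tab$estimator, tab$parent), ]
  rownames(tab) <- NULL
  p <- ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$phi, y = .data$mean_estimate, colour = .data$estimator)) +
    ggplot2::geom_hline(yintercept = unname(truth[1]), linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_estimate - 1.96 * .data$mc_se,
      ymax = .data$mean_estimate + 1.96 * .data$mc_se), width = 0.02) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parent) +
    ggplot2::labs(x = "assortment strength (phi)",
                  y = "mean estimate across replicates",
                  colour = "estimator") +
    ggplot2::theme_bw()
  list(table = tab, plot = p)
}

#' Write a bias grid table to TSV
#'
#' @param result a [runAssortmentGrid()] result (or its `table`).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBiasGrid <- function(result, path) {
  tab <- if (inherits(result, "BiasGridResult")) result$table else result
  .write_tsv(tab, path)
  invisible(path)
}

#' @importFrom ggplot2 .data
NULL
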