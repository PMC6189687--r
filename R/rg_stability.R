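#' Fit the full reference-gene stability analysis
#'
#' The package's central fitting function: filters candidates by Cp range,
#' runs the four stability estimators — [bestkeeper()], [genorm()],
#' [normfinder()] and [delta_ct()] — and aggregates their competition ranks
#' into a consensus by geometric mean ([comprehensive_ranking()]). The
#' result is a classed object with `print`, `summary`, `plot` and `coef`
#' methods.
#'
#' @param x A [cp_matrix()].
#' @param filter Apply [filter_genes_by_cp_range()] first (default `TRUE`).
#' @param low,high Cp filter bounds (cycles).
#' @param scheme Grouping scheme for [normfinder()]
#'   (default `"control_vs_treated"`); `NULL` for the ungrouped variant.
#' @param efficiency Per-gene amplification efficiency for
#'   [to_relative_quantities()] inside geNorm (default 1, perfect doubling).
#' @param genorm_cutoff Pairwise-variation cutoff (default 0.15).
#' @param dispersion BestKeeper dispersion, `"mad"` or `"sd"`.
#' @return Object of class `rg_stability`: list with `filter` (the
#'   `cp_filter`, or `NULL`), `bestkeeper`, `genorm`, `normfinder`,
#'   `delta_ct`, `consensus` (a [comprehensive_ranking()] result),
#'   `best_gene` (consensus rank 1), `best_pair` (NormFinder's),
#'   `optimal_n` (geNorm's), and `data` (the filtered matrix).
#' @examples
#' fit <- rg_stability(simulate_cp(sim_config(seed = 1)))
#' fit
#' coef(fit)
#' @export
rg_stability <- function(x, filter = TRUE, low = 15, high = 30,
                         scheme = "control_vs_treated", efficiency = 1,
                         genorm_cutoff = 0.15,
                         dispersion = c("mad", "sd")) {
  stopifnot(inherits(x, "cp_matrix"))
  flt <- NULL
  if (filter) {
    flt <- filter_genes_by_cp_range(x, low, high)
    x <- flt$matrix
  }
  bk <- bestkeeper(x, dispersion = dispersion)
  gn <- genorm(x, efficiency = efficiency, cutoff = genorm_cutoff)
  nf <- normfinder(x, scheme = scheme)
  dd <- delta_ct(x)
  cons <- comprehensive_ranking(list(bk$ranking, gn$ranking, nf$ranking,
                                     dd$ranking))
  structure(list(filter = flt, bestkeeper = bk, genorm = gn,
                 normfinder = nf, delta_ct = dd, consensus = cons,
                 best_gene = cons$gene[which.min(cons$final_rank)],
                 best_pair = nf$best_pair, optimal_n = gn$optimal_n,
                 data = x),
            class = "rg_stability")
}

#' @export
print.rg_stability <- function(x, ...) {
  cat("Reference-gene stability analysis: ", nrow(x$data$values),
      " candidates, ", ncol(x$data$values), " samples\n", sep = "")
  if (!is.null(x$filter)) {
    nex <- sum(x$filter$report$status == "excluded")
    if (nex) cat("  excluded by Cp filter: ",
                 paste(x$filter$report$gene[
                   x$filter$report$status == "excluded"], collapse = ", "),
                 "\n", sep = "")
  }
  top <- x$consensus$gene[order(x$consensus$final_rank)][1:3]
  cat("  consensus top 3:  ", paste(top, collapse = ", "), "\n", sep = "")
  cat("  best pair (model-based): ",
      paste(x$best_pair$genes, collapse = " + "), "\n", sep = "")
  cat("  reference genes needed (V <= ", x$genorm$cutoff, "): ",
      x$optimal_n, "\n", sep = "")
  invisible(x)
}

#' @export
summary.rg_stability <- function(object, ...) {
  tab <- full_stability_table(object)
  structure(list(table = tab, best_gene = object$best_gene,
                 best_pair = object$best_pair,
                 optimal_n = object$optimal_n),
            class = "summary.rg_stability")
}

#' @export
print.summary.rg_stability <- function(x, digits = 3, ...) {
  cat("Per-method statistics, ranks and consensus:\n")
  print.data.frame(x$table[order(x$table$final_rank), ],
                   row.names = FALSE, digits = digits)
  cat("\nbest gene (consensus): ", x$best_gene,
      "\nbest pair (model-based): ", paste(x$best_pair$genes,
                                           collapse = " + "),
      sprintf(" (stability %.*f)", digits, x$best_pair$stability),
      "\nreference genes needed: ", x$optimal_n, "\n", sep = "")
  invisible(x)
}

#' Consensus score of each candidate
#'
#' @param object A fitted [rg_stability()] object.
#' @param ... Ignored.
#' @return Named vector of geometric-mean rank scores (lower = more stable).
#' @export
coef.rg_stability <- function(object, ...) {
  stats::setNames(object$consensus$geo_mean, object$consensus$gene)
}

#' Combined report of all methods
#'
#' One row per gene: each method's statistic and rank, the geometric-mean
#' consensus score and the final rank.
#'
#' @param fit A fitted [rg_stability()] object.
#' @return Data frame.
#' @export
full_stability_table <- function(fit) {
  stopifnot(inherits(fit, "rg_stability"))
  g <- fit$consensus$gene
  pick <- function(st, col = "statistic")
    st[[col]][match(g, st$gene)]
  data.frame(
    gene = g,
    bestkeeper_r = pick(fit$bestkeeper$ranking),
    bestkeeper_rank = pick(fit$bestkeeper$ranking, "rank"),
    genorm_m = pick(fit$genorm$ranking),
    genorm_rank = pick(fit$genorm$ranking, "rank"),
    normfinder_stability = pick(fit$normfinder$ranking),
    normfinder_rank = pick(fit$normfinder$ranking, "rank"),
    delta_ct_fold = pick(fit$delta_ct$ranking),
    delta_ct_rank = pick(fit$delta_ct$ranking, "rank"),
    geo_mean = fit$consensus$geo_mean,
    final_rank = fit$consensus$final_rank,
    stringsAsFactors = FALSE)
}

#' Plot a stability analysis
#'
#' Two panels: consensus geometric-mean scores per gene (most stable first)
#' and the geNorm pairwise-variation curve with its cutoff.
#'
#' @param x A fitted [rg_stability()] object.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.rg_stability <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  cons <- x$consensus[order(x$consensus$geo_mean), ]
  graphics::barplot(cons$geo_mean, names.arg = cons$gene, las = 2,
                    ylab = "geometric mean of method ranks",
                    main = "Consensus stability", ...)
  vc <- x$genorm$v_curve
  graphics::plot(vc$n, vc$v, type = "b", pch = 19,
                 xlab = "n most stable genes", ylab = "V(n/n+1)",
                 main = "Pairwise variation")
  graphics::abline(h = x$genorm$cutoff, lty = 2)
  invisible(x)
}
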