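#' Per-gene descriptive Cp statistics (BestKeeper style)
#'
#' Geometric and arithmetic mean, extremes, dispersion and coefficient of
#' variation of a gene's quantification cycles. The classical dispersion for
#' this analysis is the mean absolute deviation about the arithmetic mean
#' (reported in cycles, the default here); a sample-SD alternative is
#' available. CV% is always 100 * dispersion / arithmetic mean, whichever
#' dispersion is selected.
#'
#' @param cp Numeric vector of Cp values for one gene (>= 3 non-missing,
#'   all > 0 — the geometric mean is undefined otherwise).
#' @param dispersion `"mad"` (mean absolute deviation, default) or `"sd"`
#'   (sample standard deviation, n-1 denominator).
#' @return One-row data frame: `geo_mean_cp`, `ar_mean_cp`, `min_cp`,
#'   `max_cp`, `sd_cp` (the selected dispersion), `cv_pct`.
#' @examples
#' cp_descriptive_stats(c(2, 8), dispersion = "sd")  # geo mean 4, ar mean 5
#' @export
cp_descriptive_stats <- function(cp, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  cp <- cp[!is.na(cp)]
  if (length(cp) < 2) stop("need >= 2 non-missing Cp values")
  if (any(cp <= 0)) stop("non-positive Cp: geometric mean undefined")
  ar <- mean(cp)
  disp <- if (dispersion == "mad") mean(abs(cp - ar)) else stats::sd(cp)
  data.frame(geo_mean_cp = exp(mean(log(cp))), ar_mean_cp = ar,
             min_cp = min(cp), max_cp = max(cp), sd_cp = disp,
             cv_pct = 100 * disp / ar)
}

#' BestKeeper index: per-sample geometric mean Cp
#'
#' @param x A [cp_matrix()] with complete rows for the genes used.
#' @param genes Genes entering the index (default: all). The index built over
#'   the full retained panel is the one each candidate is correlated against.
#' @return Named numeric vector, one index value per sample.
#' @export
bestkeeper_index <- function(x, genes = NULL) {
  stopifnot(inherits(x, "cp_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (nrow(v) == 0) stop("empty gene subset")
  if (anyNA(v)) stop("missing Cp values in index genes")
  exp(colMeans(log(v)))
}

#' BestKeeper stability analysis
#'
#' Computes the BestKeeper descriptive statistics for every gene, builds the
#' per-sample index (geometric mean Cp over all genes), and scores each
#' candidate by the Pearson correlation of its Cp profile with the index
#' (two-sided p-value from the exact t transform). Genes are ranked by
#' descending correlation; the sign is kept — a strongly anti-correlated
#' gene is unstable by construction. A zero-variance gene has an undefined
#' correlation and is flagged and ranked last.
#'
#' @param x A [cp_matrix()]; complete (no missing Cp), >= 3 samples.
#' @param dispersion Passed to [cp_descriptive_stats()].
#' @return Object of class `bestkeeper`: list with `table` (per-gene rows:
#'   descriptives plus `pearson_r`, `p_value`, `rank`), `index` (per-sample
#'   index) and `ranking` (a [stability_table()], direction descending).
#' @examples
#' bk <- bestkeeper(simulate_cp(sim_config(seed = 7)))
#' head(bk$table)
#' @export
bestkeeper <- function(x, dispersion = c("mad", "sd")) {
  stopifnot(inherits(x, "cp_matrix"))
  dispersion <- match.arg(dispersion)
  v <- x$values
  if (anyNA(v)) stop("BestKeeper requires a complete Cp matrix")
  if (ncol(v) < 3) stop("need >= 3 samples")
  idx <- bestkeeper_index(x)
  desc <- do.call(rbind, lapply(rownames(v), function(g)
    cp_descriptive_stats(v[g, ], dispersion)))
  r <- p <- rep.int(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    if (stats::sd(v[i, ]) == 0) next  # undefined, flagged by ranking
    ct <- stats::cor.test(v[i, ], idx, method = "pearson")
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  tab <- data.frame(gene = rownames(v), desc, pearson_r = r, p_value = p,
                    stringsAsFactors = FALSE)
  ranking <- stability_table("bestkeeper",
                             stats::setNames(r, rownames(v)),
                             "descending_better")
  tab$rank <- ranking$rank[match(tab$gene, ranking$gene)]
  rownames(tab) <- NULL
  structure(list(table = tab, index = idx, ranking = ranking,
                 dispersion = dispersion),
            class = "bestkeeper")
}

#' @export
print.bestkeeper <- function(x, digits = 3, ...) {
  cat("BestKeeper analysis (", nrow(x$table), " genes, ", length(x$index),
      " samples; dispersion: ", x$dispersion, ")\n", sep = "")
  tab <- x$table[order(x$table$rank), ]
  tab$p_value <- pmax(tab$p_value, 0.001)  # display floor
  print.data.frame(tab, row.names = FALSE, digits = digits)
  invisible(x)
}
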