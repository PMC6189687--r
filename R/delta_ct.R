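#' Comparative delta-delta-Ct stability statistic
#'
#' Descriptive per-gene statistic built from within-sample Ct differences.
#' For each sample the gene's \eqn{\Delta Ct} is taken against the
#' per-sample minimum Ct across genes (the most abundant transcript in that
#' sample acts as the within-sample control, cancelling sample-level loading
#' differences). The gene with the lowest mean \eqn{\Delta Ct} is the control
#' anchor; per-sample fold values
#' \eqn{2^{\Delta Ct_g(s) - \overline{\Delta Ct}_{control}}} are averaged
#' into the mean fold difference, and the true fold difference is its log2.
#' Genes are ranked by descending mean fold difference.
#'
#' The mean of per-sample folds is convex in \eqn{\Delta Ct}, so the mean
#' fold difference grows with both a gene's average offset from the control
#' anchor and its per-sample variability; it is a descriptive index rather
#' than a variance decomposition, and is used here as one voice in the
#' consensus.
#'
#' @param x A [cp_matrix()], complete, >= 2 genes.
#' @return Object of class `delta_ct`: list with `table` (per-gene rows:
#'   `mean_ct`, `sd`, `variance`, `ddct`, `ddct_sd`, `mean_fold`, `fold_sd`,
#'   `true_fold`, `rank`), `control_gene` (the anchor), and `ranking` (a
#'   [stability_table()] on `mean_fold`, direction descending).
#' @details Identities guaranteed at full precision: `variance == sd^2` and
#'   `true_fold == log2(mean_fold)`.
#' @examples
#' dd <- delta_ct(simulate_cp(sim_config(seed = 11)))
#' head(dd$table)
#' @export
delta_ct <- function(x) {
  stopifnot(inherits(x, "cp_matrix"))
  v <- x$values
  if (anyNA(v)) stop("delta-Ct statistic requires a complete Cp matrix")
  if (nrow(v) < 2) stop("need >= 2 genes")
  dct <- sweep(v, 2, apply(v, 2, min))      # per-sample Ct above the minimum
  mean_dct <- rowMeans(dct)
  control <- names(which.min(mean_dct))
  anchor <- mean_dct[[control]]
  folds <- 2^(dct - anchor)                 # per-sample fold vs control mean
  sd_ct <- apply(v, 1, stats::sd)
  tab <- data.frame(
    gene = rownames(v),
    mean_ct = rowMeans(v),
    sd = sd_ct,
    variance = sd_ct^2,
    ddct = anchor - mean_dct,
    ddct_sd = sd_ct,
    mean_fold = rowMeans(folds),
    fold_sd = apply(folds, 1, stats::sd),
    stringsAsFactors = FALSE)
  tab$true_fold <- log2(tab$mean_fold)
  ranking <- stability_table("delta_ct",
                             stats::setNames(tab$mean_fold, tab$gene),
                             "descending_better")
  tab$rank <- ranking$rank[match(tab$gene, ranking$gene)]
  rownames(tab) <- NULL
  structure(list(table = tab, control_gene = control, ranking = ranking),
            class = "delta_ct")
}

#' @export
print.delta_ct <- function(x, digits = 3, ...) {
  cat("Comparative delta-delta-Ct statistic (control anchor: ",
      x$control_gene, ")\n", sep = "")
  print.data.frame(x$table[order(x$table$rank), ], row.names = FALSE,
                   digits = digits)
  invisible(x)
}
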