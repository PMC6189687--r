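#' Reference-normalized fold-change time course (2^-ddCt)
#'
#' Computes a target gene's expression relative to a chosen reference gene
#' across the time course. Per sample,
#' \eqn{\Delta Ct(s) = Cp_{target}(s) - Cp_{reference}(s)}; the unanchored
#' relative quantity is \eqn{2^{-\Delta Ct(s)}}. Anchoring on the mean
#' \eqn{\Delta Ct} of the control-timepoint replicates gives
#' \eqn{\Delta\Delta Ct(s)} and the fold change
#' \eqn{2^{-\Delta\Delta Ct(s)}}, whose control-timepoint mean is 1 by
#' construction. Note that anchoring makes the fold change invariant to
#' adding a constant to the reference gene's Cp (the shift cancels in the
#' anchor); the unanchored relative quantity instead scales exactly by
#' \eqn{2^{c}} — both are reported.
#'
#' Per timepoint the series reports the mean fold, SD, SEM, replicate count
#' and a two-sided Welch t-test on the log2 fold values against the control
#' replicates (`NA` at the control timepoint itself).
#'
#' @param x A [cp_matrix()] containing both `target` and `reference` rows.
#' @param target,reference Gene identifiers.
#' @param control_timepoint Timepoint (hours) anchoring the comparison
#'   (default 0).
#' @return Object of class `fold_change_series`: list with `series`
#'   (per-timepoint data frame: `timepoint_h`, `n`, `mean_fold`, `sd_fold`,
#'   `sem_fold`, `p_vs_control`), `samples` (per-sample data frame:
#'   `sample_id`, `timepoint_h`, `dct`, `ddct`, `fold`, `rel_quantity`),
#'   `target`, `reference`, `control_timepoint`.
#' @examples
#' m <- simulate_cp(sim_config(seed = 2))
#' fc <- fold_change_series(m, target = "actb", reference = "ywhaz")
#' fc$series
#' @export
fold_change_series <- function(x, target, reference, control_timepoint = 0) {
  stopifnot(inherits(x, "cp_matrix"))
  v <- x$values
  for (g in c(target, reference))
    if (!g %in% rownames(v)) stop("gene not in matrix: ", g)
  tp <- x$samples$timepoint_h
  ctrl <- tp == control_timepoint
  if (!any(ctrl))
    stop("control timepoint ", control_timepoint, " h not present")
  dct <- v[target, ] - v[reference, ]
  if (anyNA(dct)) stop("missing Cp in target or reference row")
  ddct <- dct - mean(dct[ctrl])
  fold <- 2^(-ddct)
  persample <- data.frame(sample_id = x$samples$sample_id,
                          timepoint_h = tp, dct = dct, ddct = ddct,
                          fold = fold, rel_quantity = 2^(-dct),
                          stringsAsFactors = FALSE)
  rownames(persample) <- NULL
  lfc_ctrl <- log2(fold[ctrl])
  tps <- sort(unique(tp))
  series <- do.call(rbind, lapply(tps, function(t) {
    f <- fold[tp == t]
    p <- if (t == control_timepoint || length(f) < 2) NA_real_
         else tryCatch(stats::t.test(log2(f), lfc_ctrl)$p.value,
                       error = function(e) NA_real_)  # Welch, two-sided;
    # NA when the data are constant and the test is undefined
    data.frame(timepoint_h = t, n = length(f), mean_fold = mean(f),
               sd_fold = stats::sd(f),
               sem_fold = stats::sd(f) / sqrt(length(f)),
               p_vs_control = p)
  }))
  structure(list(series = series, samples = persample, target = target,
                 reference = reference,
                 control_timepoint = control_timepoint),
            class = "fold_change_series")
}

#' @export
print.fold_change_series <- function(x, digits = 3, ...) {
  cat("Fold-change series: ", x$target, " normalized to ", x$reference,
      " (control ", x$control_timepoint, " h)\n", sep = "")
  print.data.frame(x$series, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Plot a fold-change time course
#' @param x A [fold_change_series()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fold_change_series <- function(x, ...) {
  s <- x$series
  graphics::plot(s$timepoint_h, s$mean_fold, type = "b", pch = 19,
                 xlab = "time (h)", ylab = "fold change (2^-ddCt)",
                 main = paste(x$target, "vs", x$reference), ...)
  graphics::arrows(s$timepoint_h, s$mean_fold - s$sem_fold,
                   s$timepoint_h, s$mean_fold + s$sem_fold,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Compare normalizations across candidate reference genes
#'
#' Runs [fold_change_series()] for one target against each reference in turn
#' and tabulates the per-timepoint mean folds side by side, exposing how the
#' choice of reference gene distorts (or not) the apparent regulation of the
#' target.
#'
#' @param x A [cp_matrix()].
#' @param target Target gene identifier.
#' @param references Non-empty character vector of reference genes.
#' @param control_timepoint Passed to [fold_change_series()].
#' @return List of class `reference_comparison`: `series` (named list of
#'   [fold_change_series()] objects) and `table` (data frame, one mean-fold
#'   column per reference).
#' @export
compare_references <- function(x, target, references,
                               control_timepoint = 0) {
  if (!length(references)) stop("empty reference list")
  series <- lapply(references, function(r)
    fold_change_series(x, target, r, control_timepoint))
  names(series) <- references
  tab <- data.frame(timepoint_h = series[[1]]$series$timepoint_h)
  for (r in references) tab[[r]] <- series[[r]]$series$mean_fold
  structure(list(series = series, table = tab, target = target),
            class = "reference_comparison")
}

#' @export
print.reference_comparison <- function(x, digits = 3, ...) {
  cat("Mean fold change of ", x$target, " under each reference gene:\n",
      sep = "")
  print.data.frame(x$table, row.names = FALSE, digits = digits)
  invisible(x)
}
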