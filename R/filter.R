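#' Exclude genes outside the usable Cp range
#'
#' Quantification cycles far outside the quantitative range of the instrument
#' make a candidate unusable as a reference gene: very late crossing points
#' (mean Cp above `high`, low abundance) or very early ones (below `low`)
#' are excluded, as is any gene with a missing Cp in treated samples (failed
#' amplification under the perturbation). Bounds are strict inequalities: a
#' gene whose mean Cp equals a bound is retained.
#'
#' @param x A [cp_matrix()].
#' @param low,high Cp bounds in cycles (defaults 15 and 30).
#' @return A list of class `cp_filter` with elements
#'   \describe{
#'     \item{matrix}{the filtered `cp_matrix` (retained genes only),}
#'     \item{report}{data frame with columns `gene`, `status`
#'       (`"retained"`/`"excluded"`), `reason`, `statistic` (the offending
#'       mean Cp, or the count of missing values).}
#'   }
#' @details The mean used is the arithmetic mean of non-missing Cp. The
#'   operation is idempotent: filtering an already-filtered matrix removes
#'   nothing further.
#' @examples
#' sim <- simulate_cp(sim_config(seed = 1))
#' f <- filter_genes_by_cp_range(sim)
#' f$report
#' @export
filter_genes_by_cp_range <- function(x, low = 15, high = 30) {
  stopifnot(inherits(x, "cp_matrix"))
  if (!(low < high)) stop("'low' must be smaller than 'high'")
  v <- x$values
  treated <- x$samples$group != "control" & x$samples$timepoint_h > 0
  rows <- lapply(rownames(v), function(g) {
    cp <- v[g, ]
    mu <- mean(cp, na.rm = TRUE)
    nmiss <- sum(is.na(cp[treated]))
    if (nmiss > 0)
      data.frame(gene = g, status = "excluded",
                 reason = "missing Cp in treated samples",
                 statistic = nmiss)
    else if (mu > high)
      data.frame(gene = g, status = "excluded",
                 reason = sprintf("mean Cp > %g", high), statistic = mu)
    else if (mu < low)
      data.frame(gene = g, status = "excluded",
                 reason = sprintf("mean Cp < %g", low), statistic = mu)
    else
      data.frame(gene = g, status = "retained", reason = "", statistic = mu)
  })
  report <- do.call(rbind, rows)
  keep <- report$gene[report$status == "retained"]
  if (!length(keep))
    stop("all genes excluded by the Cp range filter; review thresholds (",
         low, ", ", high, ")")
  structure(list(matrix = x[keep, ], report = report), class = "cp_filter")
}

#' @export
print.cp_filter <- function(x, ...) {
  exc <- x$report[x$report$status == "excluded", , drop = FALSE]
  cat("Cp range filter: ", sum(x$report$status == "retained"), " retained, ",
      nrow(exc), " excluded\n", sep = "")
  if (nrow(exc))
    for (i in seq_len(nrow(exc)))
      cat(sprintf("  - %s: %s (%.4g)\n", exc$gene[i], exc$reason[i],
                  exc$statistic[i]))
  invisible(x)
}

#' Partition samples into groups
#'
#' Builds the sample grouping used by grouped stability estimation (NormFinder
#' style). Three schemes are supported:
#' \describe{
#'   \item{`by_group_column`}{use the `group` column of the sample sheet;}
#'   \item{`control_vs_treated`}{timepoint 0 h is the control group, every
#'     later timepoint is treated;}
#'   \item{`by_timepoint`}{one group per timepoint.}
#' }
#'
#' @param x A [cp_matrix()].
#' @param scheme Grouping rule (see Details).
#' @param require_replicated If `TRUE` (default), fail unless there are at
#'   least two groups with two or more samples each — the minimum a grouped
#'   variance decomposition needs.
#' @return Named list mapping group label to an integer vector of sample
#'   indices; a partition of `seq_len(ncol(x))`.
#' @export
split_groups <- function(x,
                         scheme = c("control_vs_treated", "by_group_column",
                                    "by_timepoint"),
                         require_replicated = TRUE) {
  stopifnot(inherits(x, "cp_matrix"))
  scheme <- match.arg(scheme)
  s <- x$samples
  lab <- switch(scheme,
    by_group_column = as.character(s$group),
    control_vs_treated = ifelse(s$timepoint_h == 0, "control", "treated"),
    by_timepoint = sprintf("t%gh", s$timepoint_h))
  groups <- split(seq_len(nrow(s)), lab)
  if (require_replicated) {
    big <- sum(lengths(groups) >= 2)
    if (length(groups) < 2 || big < 2)
      stop("grouped analysis needs >= 2 groups with >= 2 samples each; ",
           "scheme '", scheme, "' gives ", length(groups), " group(s)")
  }
  groups
}
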