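#' Published summary tables from a Busulfan endothelial-injury RG screen
#'
#' Plain-text copies of the published summary statistics from an RT-qPCR
#' reference-gene screen in Busulfan-injured mouse bEnd.3 endothelial cells
#' (13 candidate housekeeping genes, 0-72 h time course, 3 replicates; raw
#' Cp replicates were not published). Shipped with the package as worked
#' input for the deterministic identities the consensus machinery must
#' satisfy, and as a realistic target for the simulator.
#'
#' Available tables:
#' \describe{
#'   \item{`ranks`}{per-method statistic + competition rank for each of the
#'     four methods, plus the published geometric-mean score and final rank;}
#'   \item{`bestkeeper`}{per-gene descriptives (geometric/arithmetic mean,
#'     min, max, dispersion, CV%), index correlation and p-value;}
#'   \item{`delta_ct`}{per-gene mean Ct, SD, variance, ddCt +/- SD, mean and
#'     true (log2) fold difference;}
#'   \item{`standard_curves`}{per-primer R^2, slope and efficiency; the
#'     `consistent` column flags the rows whose printed slope and efficiency
#'     satisfy E = 10^(-1/A) - 1 (the remainder carry typographical slopes
#'     or efficiencies and are unusable as fixtures).}
#' }
#'
#' @param name Which table to load.
#' @return Data frame.
#' @examples
#' head(published_stability_tables("ranks"))
#' @export
published_stability_tables <- function(name = c("ranks", "bestkeeper",
                                                "delta_ct",
                                                "standard_curves")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("busulfan_ec_", name, ".tsv"),
                      package = "rgstab", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
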