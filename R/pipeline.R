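#' Pipeline configuration
#'
#' @param cp_table,sample_sheet Input paths (delimited text); alternatively
#'   supply `data`, an in-memory [cp_matrix()].
#' @param data Optional [cp_matrix()] used instead of reading files.
#' @param out_dir Output directory (created if needed).
#' @param sep Delimiter of the input files.
#' @param scheme Grouping scheme for the model-based method.
#' @param low,high Cp filter bounds.
#' @param genorm_cutoff Pairwise-variation cutoff (> 0).
#' @param efficiency Per-gene efficiency vector or single value.
#' @param targets Optional character vector of target genes to normalize
#'   against the consensus best gene.
#' @param report_digits Decimal places for the human-readable report file
#'   (default 2; p-values are floored at 0.001 there). Machine-readable
#'   outputs always keep full precision.
#' @return List of class `run_config`.
#' @export
run_config <- function(cp_table = NULL, sample_sheet = NULL, data = NULL,
                       out_dir = tempfile("rgstab_run_"), sep = "\t",
                       scheme = "control_vs_treated", low = 15, high = 30,
                       genorm_cutoff = 0.15, efficiency = 1,
                       targets = NULL, report_digits = 2) {
  if (is.null(data) && (is.null(cp_table) || is.null(sample_sheet)))
    stop("supply either 'data' or both 'cp_table' and 'sample_sheet'")
  if (genorm_cutoff <= 0) stop("genorm_cutoff must be > 0")
  if (!(low < high)) stop("'low' must be smaller than 'high'")
  structure(list(cp_table = cp_table, sample_sheet = sample_sheet,
                 data = data, out_dir = out_dir, sep = sep, scheme = scheme,
                 low = low, high = high, genorm_cutoff = genorm_cutoff,
                 efficiency = efficiency, targets = targets,
                 report_digits = report_digits),
            class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(format(d, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full stability pipeline and write its reports
#'
#' Executes filter, all four stability methods and the consensus (plus
#' optional target-gene normalization), and writes every artifact to
#' `config$out_dir`: per-method tables, the consensus table, the
#' pairwise-variation curve, the filter report, a rounded human-readable
#' report, a JSON summary (best gene, best pair, optimal gene count, any
#' tie/clamp events), and a manifest listing each file with its MD5 hash.
#' Outputs are deterministic for a fixed input; notable choices actually
#' taken (grouping scheme, removal ties, variance clamps) are recorded in
#' the summary.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest data frame (`file`, `md5`). The fitted
#'   [rg_stability()] object is attached as attribute `fit`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- if (!is.null(config$data)) config$data
       else read_cp_table(config$cp_table, config$sample_sheet, config$sep)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- rg_stability(x, low = config$low, high = config$high,
                      scheme = config$scheme,
                      efficiency = config$efficiency,
                      genorm_cutoff = config$genorm_cutoff)
  od <- function(f) file.path(config$out_dir, f)
  files <- c(
    write_tsv(fit$filter$report, od("filter_report.tsv")),
    write_tsv(fit$bestkeeper$table, od("bestkeeper.tsv")),
    write_tsv(as.data.frame(fit$genorm$ranking), od("genorm.tsv")),
    write_tsv(fit$genorm$v_curve, od("genorm_v_curve.tsv")),
    write_tsv(as.data.frame(fit$normfinder$ranking), od("normfinder.tsv")),
    write_tsv(fit$delta_ct$table, od("delta_ct.tsv")),
    write_tsv(as.data.frame(fit$consensus), od("consensus.tsv")))
  full <- full_stability_table(fit)
  files <- c(files, write_tsv(full, od("stability_full.tsv")))
  # human-readable report: rounded, p-values floored at 0.001
  rep_bk <- fit$bestkeeper$table
  rep_bk$p_value <- pmax(rep_bk$p_value, 0.001)
  num <- vapply(rep_bk, is.numeric, logical(1)) & names(rep_bk) != "p_value"
  rep_bk[num] <- round(rep_bk[num], config$report_digits)
  rep_bk$p_value <- round(rep_bk$p_value, 3)
  files <- c(files, write_tsv(rep_bk, od("report_bestkeeper.tsv")))
  if (!is.null(config$targets)) {
    for (tg in config$targets) {
      fc <- fold_change_series(fit$data, tg, fit$best_gene)
      files <- c(files,
                 write_tsv(fc$series, od(sprintf("foldchange_%s.tsv", tg))))
    }
  }
  summ <- list(best_gene = fit$best_gene,
               best_pair = fit$best_pair$genes,
               best_pair_stability = fit$best_pair$stability,
               optimal_gene_count = fit$optimal_n,
               scheme = config$scheme,
               excluded_genes = fit$filter$report$gene[
                 fit$filter$report$status == "excluded"],
               genorm_removal_ties = nrow(fit$genorm$ties),
               normfinder_variance_clamps = fit$normfinder$n_clamped)
  jsonlite::write_json(summ, od("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "list")
  files <- c(files, od("summary.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, od("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(manifest, "fit") <- fit
  invisible(manifest)
}
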