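#' Candidate-gene specification for the Cp simulator
#'
#' Describes one simulated candidate reference gene. Expression bands follow
#' the two abundance classes seen in cultured endothelial cells: highly
#' expressed candidates cross threshold at 21-24 cycles, moderately expressed
#' ones at 26-28 cycles.
#'
#' @param name Gene identifier.
#' @param baseline_cp Baseline quantification cycle at 0 h; must lie inside
#'   the declared band.
#' @param band `"high"` (21-24 cycles) or `"moderate"` (26-28 cycles).
#' @param drift_per_72h Gene-specific systematic Cp shift (cycles) over the
#'   full 72 h time course, applied linearly in time. A drift shared by the
#'   whole panel is stability-neutral (it cancels in ratios); a gene whose
#'   drift deviates from the panel's is unstable.
#' @param instability_sd SD (cycles) of gene-specific per-sample perturbation;
#'   the knob that makes a gene biologically unstable.
#' @param is_stable_truth Ground-truth label used by recovery tests.
#' @return One-row data frame.
#' @export
gene_spec <- function(name, baseline_cp, band = c("high", "moderate"),
                      drift_per_72h = 0, instability_sd = 0,
                      is_stable_truth = TRUE) {
  band <- match.arg(band)
  lim <- if (band == "high") c(21, 24) else c(26, 28)
  if (baseline_cp < lim[1] || baseline_cp > lim[2])
    stop("baseline_cp ", baseline_cp, " outside the '", band, "' band [",
         lim[1], ", ", lim[2], "]")
  if (instability_sd < 0) stop("instability_sd must be >= 0")
  data.frame(name = name, baseline_cp = baseline_cp, band = band,
             drift_per_72h = drift_per_72h, instability_sd = instability_sd,
             is_stable_truth = is_stable_truth, stringsAsFactors = FALSE)
}

#' Default 13-gene simulated panel
#'
#' A panel emulating a typical housekeeping-gene screen in Busulfan-injured
#' endothelial cells: seven highly and six moderately expressed candidates, a
#' shared injury-driven upward drift of about 3 cycles over 72 h for the
#' stable genes, and three designated unstable genes (`gapdh`, `tbp`, `ubc`)
#' whose drift decouples from the panel and whose per-sample perturbation SD
#' is elevated.
#'
#' @return Data frame of [gene_spec()] rows.
#' @export
default_gene_panel <- function() {
  rbind(
    gene_spec("actb",  21.3, "high",     3.2, 0.15),
    gene_spec("gapdh", 21.5, "high",     0.8, 0.60, is_stable_truth = FALSE),
    gene_spec("rplp0", 21.6, "high",     2.8, 0.15),
    gene_spec("b2m",   22.3, "high",     3.0, 0.15),
    gene_spec("ppia",  22.5, "high",     2.9, 0.15),
    gene_spec("ubc",   22.8, "high",     1.2, 0.70, is_stable_truth = FALSE),
    gene_spec("ywhaz", 23.2, "high",     3.3, 0.15),
    gene_spec("gusb",  26.3, "moderate", 2.7, 0.15),
    gene_spec("tfrc",  26.8, "moderate", 3.1, 0.15),
    gene_spec("alas1", 27.2, "moderate", 3.4, 0.15),
    gene_spec("tbp",   27.3, "moderate", 0.3, 0.50, is_stable_truth = FALSE),
    gene_spec("hprt1", 27.5, "moderate", 3.2, 0.15),
    gene_spec("hmbs",  27.9, "moderate", 2.6, 0.15)
  )
}

#' Simulation configuration
#'
#' @param genes Data frame of [gene_spec()] rows
#'   (default [default_gene_panel()]).
#' @param timepoints_h Observation times in hours
#'   (default `c(0, 12, 24, 36, 48, 72)`).
#' @param replicates Independent replicates per timepoint (default 3,
#'   minimum 2).
#' @param shared_shift_sd SD (cycles) of a per-sample shift common to all
#'   genes — template loading / RNA quality variation (default 1.5). This is
#'   the dominant source of raw Cp spread, and is exactly what reference-gene
#'   normalization is meant to remove.
#' @param replicate_noise_sd SD (cycles) of independent per-well technical
#'   noise (default 0.25).
#' @param seed Integer seed; identical configurations produce identical
#'   matrices.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genes = default_gene_panel(),
                       timepoints_h = c(0, 12, 24, 36, 48, 72),
                       replicates = 3, shared_shift_sd = 1.5,
                       replicate_noise_sd = 0.25, seed = 1L) {
  stopifnot(is.data.frame(genes))
  if (anyDuplicated(genes$name)) stop("duplicate gene names in panel")
  if (replicates < 2) stop("replicates must be >= 2")
  if (shared_shift_sd < 0 || replicate_noise_sd < 0 ||
      any(genes$instability_sd < 0))
    stop("all SDs must be >= 0")
  if (any(timepoints_h < 0)) stop("timepoints_h must be non-negative")
  structure(list(genes = genes, timepoints_h = timepoints_h,
                 replicates = as.integer(replicates),
                 shared_shift_sd = shared_shift_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a Cp dataset
#'
#' Generates quantification cycles under an additive model on the Cp (log2
#' expression) scale:
#' \deqn{Cp(g, s) = b_g + d_g t_s/72 + u_s + e_{gs} + w_{gs}}
#' with gene baseline \eqn{b_g}, gene drift \eqn{d_g} applied linearly in
#' time, a shared per-sample shift \eqn{u_s \sim N(0, \sigma_u^2)} drawn once
#' per sample and applied to all genes, gene-specific instability
#' \eqn{e_{gs} \sim N(0, \sigma_g^2)} and technical noise
#' \eqn{w_{gs} \sim N(0, \sigma_w^2)}. A multiplicative model for expression
#' is exactly additive in cycles, which is why all stability statistics
#' operate on this scale.
#'
#' @param config A [sim_config()].
#' @return A [cp_matrix()] with samples labelled `t<h>h_r<rep>`, group
#'   `"control"` at 0 h and `"treated"` later.
#' @examples
#' m <- simulate_cp(sim_config(seed = 42))
#' dim(m)
#' @export
simulate_cp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genes
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      timepoint_h = config$timepoints_h)
  grid <- grid[order(grid$timepoint_h, grid$replicate), , drop = FALSE]
  ns <- nrow(grid)
  ng <- nrow(g)
  samples <- data.frame(
    sample_id = sprintf("t%gh_r%d", grid$timepoint_h, grid$replicate),
    group = ifelse(grid$timepoint_h == 0, "control", "treated"),
    timepoint_h = grid$timepoint_h,
    replicate = grid$replicate,
    stringsAsFactors = FALSE)
  v <- with_seed(config$seed, {
    shared <- stats::rnorm(ns, 0, config$shared_shift_sd)
    base <- outer(g$baseline_cp, rep(1, ns)) +
      outer(g$drift_per_72h, grid$timepoint_h / 72) +
      outer(rep(1, ng), shared)
    pert <- matrix(stats::rnorm(ng * ns, 0, rep(g$instability_sd, ns)),
                   nrow = ng)
    well <- matrix(stats::rnorm(ng * ns, 0, config$replicate_noise_sd),
                   nrow = ng)
    base + pert + well
  })
  dimnames(v) <- list(g$name, samples$sample_id)
  cp_matrix(v, samples)
}

#' Ground-truth stability labels of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Named logical vector, `TRUE` for genes declared stable. Purely a
#'   deterministic extraction from the configuration; independent of the seed.
#' @export
truth_labels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stats::setNames(as.logical(config$genes$is_stable_truth),
                  config$genes$name)
}
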