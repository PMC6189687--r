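# Small deterministic fixtures built in code.

# cp_matrix from a bare matrix, with a default time-course sample sheet
make_cp <- function(values, timepoint_h = NULL, group = NULL) {
  ns <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ns))
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(timepoint_h)) timepoint_h <- rep(c(0, 24, 48), length.out = ns)
  if (is.null(group)) group <- ifelse(timepoint_h == 0, "control", "treated")
  cp_matrix(values, data.frame(sample_id = colnames(values), group = group,
                               timepoint_h = timepoint_h,
                               replicate = stats::ave(seq_len(ns),
                                                      timepoint_h,
                                                      FUN = seq_along)))
}

# random complete Cp matrix (genes x samples) in a realistic range
rand_cp <- function(ng, ns, seed) {
  set.seed(seed)
  v <- matrix(runif(ng * ns, 18, 30), ng, ns,
              dimnames = list(paste0("g", seq_len(ng)),
                              paste0("s", seq_len(ns))))
  make_cp(v, timepoint_h = rep(c(0, 12, 24, 36, 48, 72), length.out = ns))
}

# the recovery panel: 10 stable candidates (instability SD 0.1) and 3
# unstable ones (SD 1.0), spread over both expression bands
recovery_panel <- function() {
  stable <- rbind(
    gene_spec("s01", 21.5, "high", instability_sd = 0.1),
    gene_spec("s02", 22.0, "high", instability_sd = 0.1),
    gene_spec("s03", 22.5, "high", instability_sd = 0.1),
    gene_spec("s04", 23.0, "high", instability_sd = 0.1),
    gene_spec("s05", 23.5, "high", instability_sd = 0.1),
    gene_spec("s06", 26.2, "moderate", instability_sd = 0.1),
    gene_spec("s07", 26.6, "moderate", instability_sd = 0.1),
    gene_spec("s08", 27.0, "moderate", instability_sd = 0.1),
    gene_spec("s09", 27.4, "moderate", instability_sd = 0.1),
    gene_spec("s10", 27.8, "moderate", instability_sd = 0.1))
  unstable <- rbind(
    gene_spec("u01", 22.8, "high", instability_sd = 1, is_stable_truth = FALSE),
    gene_spec("u02", 24.0, "high", instability_sd = 1, is_stable_truth = FALSE),
    gene_spec("u03", 26.8, "moderate", instability_sd = 1,
              is_stable_truth = FALSE))
  rbind(stable, unstable)
}

# fraction of seeded datasets whose consensus puts every unstable gene in the
# bottom `k` positions (largest geometric-mean scores)
recovery_rate <- function(n_seeds, k = 5, seed_offset = 0) {
  genes <- recovery_panel()
  truth <- c("u01", "u02", "u03")
  hits <- 0
  for (s in seq_len(n_seeds)) {
    m <- simulate_cp(sim_config(genes = genes, seed = s + seed_offset))
    fit <- rg_stability(m, filter = FALSE)
    worst <- fit$consensus$gene[order(fit$consensus$geo_mean,
                                      decreasing = TRUE)][seq_len(k)]
    if (all(truth %in% worst)) hits <- hits + 1
  }
  hits / n_seeds
}
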