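#' Model-based (NormFinder-style) stability estimation
#'
#' Decomposes each candidate gene's variation into intra-group variance and
#' inter-group deviation, following the model-based ANOVA approach used for
#' reference-gene selection. Cp values are already on a log (cycle) scale, so
#' they enter the model directly.
#'
#' Within each group the model is \eqn{y_{ij} = \mu_i + b_j + e_{ij}} (gene
#' effect, sample effect, noise with gene-specific variance
#' \eqn{\sigma_i^2}). Because the per-sample average over genes used to
#' remove \eqn{b_j} contains a share of every gene's own noise, the raw
#' residual variance \eqn{\hat s_i^2 = RSS_i / (n_g - 1)} is biased; the
#' corrected estimate is
#' \deqn{\hat\sigma_i^2 = \left(\hat s_i^2 - \frac{\bar s^2}{G - 1}\right)
#'   \frac{G}{G - 2},}
#' clamped at zero (clamping is counted and reported). The inter-group
#' deviation \eqn{d_{ig}} is the gene's group mean, centered on the group's
#' across-gene mean and then on the gene's own across-group mean; deviations
#' are shrunk toward zero by the variance ratio
#' \eqn{\hat\tau^2 / (\hat\tau^2 + \hat\sigma_i^2 / n_g)}, with
#' \eqn{\hat\tau^2} a method-of-moments estimate of the true inter-group
#' variance (clamped at zero). The stability value is
#' \deqn{\rho_i = \frac{1}{K}\sum_g \left(|\tilde d_{ig}| +
#'   \sqrt{\hat\sigma_i^2 / n_g}\right);}
#' lower is more stable. For a gene set the shrunken deviations average
#' (opposite-sign deviations cancel — the reason a pair can beat the best
#' single gene) and the SE term pools the variances; the best pair is found
#' by exhaustive search.
#'
#' With a single group (or `groups = NULL` and an unreplicated design) the
#' ungrouped variant is used: stability reduces to the intra-group SE term,
#' whose ordering equals ordering by the SD of sample-centered residuals.
#'
#' @param x A [cp_matrix()], complete, >= 3 genes.
#' @param groups Named list of sample-index vectors (a partition, e.g. from
#'   [split_groups()]); `NULL` derives it from `scheme`. Pass a single group
#'   (or set `scheme = NULL`) for the ungrouped variant.
#' @param scheme Grouping scheme handed to [split_groups()] when `groups` is
#'   `NULL`; default `"control_vs_treated"` (0 h = control). `NULL` means
#'   ungrouped.
#' @return Object of class `normfinder`: list with `stability` (named
#'   vector), `intragroup_var` and `intergroup_dev` (+ `shrunken_dev`)
#'   matrices (gene x group), `best_gene`, `best_pair` (list: `genes`,
#'   `stability`), `ranking` (a [stability_table()]), `grouped`,
#'   `n_clamped`.
#' @examples
#' nf <- normfinder(simulate_cp(sim_config(seed = 5)))
#' nf$best_gene
#' nf$best_pair
#' @export
normfinder <- function(x, groups = NULL, scheme = "control_vs_treated") {
  stopifnot(inherits(x, "cp_matrix"))
  v <- x$values
  if (anyNA(v)) stop("NormFinder requires a complete Cp matrix")
  ng <- nrow(v)
  if (ng < 3) stop("need >= 3 genes")
  if (is.null(groups)) {
    groups <- if (is.null(scheme)) list(all = seq_len(ncol(v)))
              else split_groups(x, scheme)
  }
  idx_all <- sort(unlist(groups, use.names = FALSE))
  if (!identical(idx_all, seq_len(ncol(v))))
    stop("'groups' must partition the samples")
  grouped <- length(groups) >= 2
  if (!grouped && !is.null(scheme) && length(groups) == 1)
    warning("only one group; falling back to the ungrouped variant")
  if (grouped && any(lengths(groups) < 2))
    stop("every group needs >= 2 samples")
  K <- length(groups)
  sig2 <- dev <- matrix(0, ng, K, dimnames = list(rownames(v), names(groups)))
  nk <- lengths(groups)
  n_clamped <- 0L
  for (k in seq_len(K)) {
    d <- v[, groups[[k]], drop = FALSE]
    n <- ncol(d)
    r <- d - rowMeans(d) - rep(colMeans(d), each = ng) + mean(d)
    s2 <- rowSums(r^2) / (n - 1)
    est <- (s2 - mean(s2) / (ng - 1)) * ng / (ng - 2)
    n_clamped <- n_clamped + sum(est < 0)
    sig2[, k] <- pmax(est, 0)
    dev[, k] <- rowMeans(d) - mean(d)
  }
  dev <- dev - rowMeans(dev)  # center each gene across groups
  se2 <- sweep(sig2, 2, nk, "/")
  if (grouped) {
    tau2 <- max(0, sum(dev^2) / ((ng - 1) * (K - 1)) - mean(se2))
    shr <- dev * tau2 / (tau2 + se2)
    if (tau2 == 0) shr[] <- 0
  } else {
    shr <- dev  # all zero: single group has no between-group deviation
  }
  set_stability <- function(gs) {
    mean(abs(colMeans(shr[gs, , drop = FALSE])) +
           sqrt(colSums(se2[gs, , drop = FALSE])) / length(gs))
  }
  stab <- vapply(rownames(v), function(g) set_stability(g), numeric(1))
  pairs <- utils::combn(rownames(v), 2)
  pstab <- apply(pairs, 2, set_stability)
  bp <- which.min(pstab)
  ranking <- stability_table("normfinder", stab, "ascending_better")
  structure(list(stability = stab, intragroup_var = sig2,
                 intergroup_dev = dev, shrunken_dev = shr,
                 group_sizes = nk, grouped = grouped,
                 best_gene = names(which.min(stab)),
                 best_pair = list(genes = pairs[, bp],
                                  stability = unname(pstab[bp])),
                 ranking = ranking, n_clamped = n_clamped),
            class = "normfinder")
}

#' Combined stability of a gene set (NormFinder)
#'
#' Stability of using several genes jointly as the normalization factor:
#' shrunken inter-group deviations are averaged over the set (so deviations
#' of opposite sign cancel) and the intra-group SE term pools the variances.
#'
#' @param object A fitted [normfinder()] object.
#' @param gene_set Character vector of >= 1 gene identifiers.
#' @return Combined stability value (lower = better).
#' @export
normfinder_set_stability <- function(object, gene_set) {
  stopifnot(inherits(object, "normfinder"))
  miss <- setdiff(gene_set, rownames(object$shrunken_dev))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  se2 <- sweep(object$intragroup_var, 2, object$group_sizes, "/")
  mean(abs(colMeans(object$shrunken_dev[gene_set, , drop = FALSE])) +
         sqrt(colSums(se2[gene_set, , drop = FALSE])) / length(gene_set))
}

#' @export
print.normfinder <- function(x, digits = 3, ...) {
  cat("NormFinder-style stability (",
      if (x$grouped) paste0(length(x$group_sizes), " groups") else
        "ungrouped", ")\n", sep = "")
  ord <- order(x$stability)
  print(round(x$stability[ord], digits))
  cat("  best gene: ", x$best_gene, "\n  best pair: ",
      paste(x$best_pair$genes, collapse = " + "),
      sprintf(" (stability %.*f)\n", digits, x$best_pair$stability),
      sep = "")
  if (x$n_clamped)
    cat("  note:", x$n_clamped, "negative variance estimate(s) clamped to 0\n")
  invisible(x)
}
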