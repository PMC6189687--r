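#' Convert Cp values to relative quantities
#'
#' Transforms quantification cycles into relative expression quantities
#' \deqn{Q(g, s) = (1 + E_g)^{Cp_{min}(g) - Cp(g, s)},} anchored on each
#' gene's minimum Cp so that the maximum quantity per gene is 1 (the anchor
#' cancels in every ratio-based statistic; it is chosen purely for numeric
#' range). The default efficiency E = 1 assumes perfect doubling.
#'
#' @param x A [cp_matrix()] (complete) or a numeric genes x samples matrix.
#' @param efficiency Amplification efficiency: a single value or a named
#'   per-gene vector, each in (0, +); default 1.
#' @return Matrix of class `rq_matrix` (genes x samples, all values in
#'   (0, 1]), with attributes `efficiency` (per-gene vector) and `anchor`
#'   (`"min_cp"`).
#' @examples
#' q <- to_relative_quantities(rbind(g = c(s1 = 20, s2 = 21, s3 = 23)))
#' q  # 1, 0.5, 0.125
#' @export
to_relative_quantities <- function(x, efficiency = 1) {
  v <- if (inherits(x, "cp_matrix")) x$values else as.matrix(x)
  if (anyNA(v)) stop("missing Cp values; filter or impute first")
  if (is.null(names(efficiency))) {
    eff <- rep_len(efficiency, nrow(v))
    names(eff) <- rownames(v)
  } else {
    miss <- setdiff(rownames(v), names(efficiency))
    if (length(miss))
      stop("no efficiency for gene(s): ", paste(miss, collapse = ", "))
    eff <- efficiency[rownames(v)]
  }
  if (any(!is.finite(eff)) || any(1 + eff <= 1))
    stop("efficiencies must be finite and > 0")
  q <- (1 + eff)^(apply(v, 1, min) - v)
  structure(q, efficiency = eff, anchor = "min_cp",
            class = c("rq_matrix", class(q)))
}

as_rq <- function(x, efficiency = 1) {
  if (inherits(x, "rq_matrix")) x else to_relative_quantities(x, efficiency)
}

#' geNorm expression stability measure M
#'
#' For gene \eqn{g}, \eqn{M_g} is the mean over all other genes \eqn{k} of
#' the sample standard deviation (n-1 denominator) of the pairwise log2
#' ratios \eqn{\log_2(Q_g / Q_k)}. Genes whose expression tracks the rest of
#' the panel have constant log ratios and small M; lower M = more stable.
#'
#' @param q An `rq_matrix` from [to_relative_quantities()], or a
#'   [cp_matrix()] (converted with efficiency 1).
#' @param gene Optional single gene; default computes M for every gene.
#' @return Named numeric vector of M values (or a single value).
#' @export
genorm_m <- function(q, gene = NULL) {
  q <- as_rq(q)
  if (nrow(q) < 2) stop("M requires >= 2 genes")
  if (ncol(q) < 3) stop("M requires >= 3 samples")
  a <- log2(q)
  gset <- if (is.null(gene)) rownames(q) else gene
  m <- vapply(gset, function(g) {
    others <- setdiff(rownames(q), g)
    mean(vapply(others, function(k) stats::sd(a[g, ] - a[k, ]),
                numeric(1)))
  }, numeric(1))
  if (is.null(gene)) m else unname(m)
}

#' geNorm analysis: stepwise ranking and pairwise variation
#'
#' Runs the full geNorm procedure: computes M on the complete panel, then
#' iteratively removes the single least stable gene (highest M, recomputing M
#' on the survivors) until two genes remain. The final two genes cannot be
#' distinguished (their M values are identical by construction) and jointly
#' share rank 1. The pairwise-variation curve V(n/n+1) compares normalization
#' factors built from the n and n+1 most stable genes and drives the choice
#' of how many reference genes to use.
#'
#' @param x A [cp_matrix()] or `rq_matrix` (>= 3 genes).
#' @param efficiency Passed to [to_relative_quantities()] when `x` is a Cp
#'   matrix.
#' @param cutoff V threshold below which adding a further gene is unnecessary
#'   (default 0.15).
#' @return Object of class `genorm`: list with
#'   \describe{
#'     \item{m_values}{M for every gene on the full panel,}
#'     \item{m_at_removal}{M of each gene on the panel it was removed from
#'       (the final pair share the last value),}
#'     \item{exclusion_order}{genes removed, least stable first,}
#'     \item{final_pair}{the two surviving genes,}
#'     \item{v_curve}{data frame `n`, `v` for n = 2..G-1,}
#'     \item{optimal_n}{smallest n with V <= cutoff (G, with a warning, if
#'       none),}
#'     \item{ranking}{a [stability_table()] (exclusion-order ranks; the final
#'       pair shares rank 1),}
#'     \item{ties}{data frame logging any removal tie broken by input order.}
#'   }
#' @examples
#' gn <- genorm(simulate_cp(sim_config(seed = 3)))
#' gn$final_pair
#' gn$v_curve
#' @export
genorm <- function(x, efficiency = 1, cutoff = 0.15) {
  q <- as_rq(x, efficiency)
  if (nrow(q) < 3) stop("geNorm stepwise ranking requires >= 3 genes")
  m_full <- genorm_m(q)
  remaining <- rownames(q)
  excluded <- character(0)
  m_removal <- numeric(0)
  ties <- data.frame(step = integer(0), tied = character(0),
                     removed = character(0))
  step <- 0L
  while (length(remaining) > 2) {
    step <- step + 1L
    m <- genorm_m(q[remaining, , drop = FALSE])
    worst <- which(m == max(m))
    if (length(worst) > 1)  # tie: drop the later gene in input order
      ties <- rbind(ties, data.frame(
        step = step, tied = paste(names(m)[worst], collapse = ","),
        removed = names(m)[worst[length(worst)]]))
    drop <- names(m)[worst[length(worst)]]
    excluded <- c(excluded, drop)
    m_removal <- c(m_removal, stats::setNames(m[[drop]], drop))
    remaining <- setdiff(remaining, drop)
  }
  pair_m <- genorm_m(q[remaining, , drop = FALSE])
  m_removal <- c(m_removal, pair_m)
  # most stable first: the final pair, then the exclusions in reverse
  stable_order <- c(remaining, rev(excluded))
  ranks <- stats::setNames(c(1L, 1L, seq_along(excluded) + 2L), stable_order)
  ranking <- structure(
    data.frame(gene = stable_order,
               statistic = unname(m_removal[stable_order]),
               rank = unname(ranks), stringsAsFactors = FALSE),
    method = "genorm", direction = "ascending_better",
    class = c("stability_table", "data.frame"))
  vc <- pairwise_variation(q, stable_order)
  res <- structure(list(m_values = m_full, m_at_removal = m_removal,
                        exclusion_order = excluded, final_pair = remaining,
                        v_curve = vc, cutoff = cutoff, ranking = ranking,
                        ties = ties),
                   class = "genorm")
  res$optimal_n <- optimal_gene_count(vc, cutoff)
  res
}

#' Pairwise variation curve V(n/n+1)
#'
#' \eqn{NF_n(s)} is the geometric mean of relative quantities over the n most
#' stable genes; \eqn{V_{n/n+1}} is the sample SD across samples of
#' \eqn{\log_2(NF_n / NF_{n+1})}, for n = 2..G-1. Small V means the (n+1)-th
#' gene barely changes the normalization factor.
#'
#' @param q An `rq_matrix` (or [cp_matrix()], converted with efficiency 1).
#' @param stable_order Gene identifiers ordered most stable first (e.g. from
#'   [genorm()]).
#' @return Data frame with columns `n` and `v`.
#' @export
pairwise_variation <- function(q, stable_order) {
  q <- as_rq(q)
  if (!setequal(stable_order, rownames(q)))
    stop("'stable_order' must be a permutation of the genes")
  g <- length(stable_order)
  if (g < 3) stop("pairwise variation requires >= 3 genes")
  a <- log2(q[stable_order, , drop = FALSE])
  nf <- function(n) colMeans(a[seq_len(n), , drop = FALSE])  # log2 NF_n
  data.frame(n = 2:(g - 1),
             v = vapply(2:(g - 1),
                        function(n) stats::sd(nf(n) - nf(n + 1)),
                        numeric(1)))
}

#' Optimal number of reference genes from a V curve
#'
#' @param v_curve Data frame `n`, `v` from [pairwise_variation()].
#' @param cutoff V threshold (default 0.15).
#' @return Smallest `n` with `v <= cutoff`; if the whole curve is above the
#'   cutoff, the total gene count (max n + 1) with a warning.
#' @export
optimal_gene_count <- function(v_curve, cutoff = 0.15) {
  stopifnot(nrow(v_curve) >= 1, cutoff > 0)
  ok <- which(v_curve$v <= cutoff)
  if (length(ok)) return(as.integer(v_curve$n[ok[1]]))
  g <- as.integer(max(v_curve$n) + 1)
  warning("no V(n/n+1) below cutoff ", cutoff, "; using all ", g, " genes")
  g
}

#' @export
print.genorm <- function(x, digits = 3, ...) {
  cat("geNorm analysis (", length(x$m_values), " genes)\n", sep = "")
  cat("  most stable pair: ", paste(x$final_pair, collapse = " & "),
      sprintf(" (M = %.*f)", digits, x$m_at_removal[[x$final_pair[1]]]),
      "\n", sep = "")
  cat("  exclusion order (least stable first): ",
      paste(x$exclusion_order, collapse = ", "), "\n", sep = "")
  cat("  optimal gene count (V <= ", x$cutoff, "): ", x$optimal_n, "\n",
      sep = "")
  print(x$v_curve, row.names = FALSE, digits = digits)
  if (nrow(x$ties)) cat("  note:", nrow(x$ties), "removal tie(s) broken by",
                        "input order\n")
  invisible(x)
}
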