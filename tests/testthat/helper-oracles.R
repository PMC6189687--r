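# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops and textbook formulas only.

# geNorm M by explicit pairwise loops
oracle_m <- function(q) {
  a <- log2(q)
  g <- rownames(q)
  out <- numeric(length(g))
  names(out) <- g
  for (i in g) {
    sds <- c()
    for (k in setdiff(g, i)) {
      ratio <- a[i, ] - a[k, ]
      mu <- sum(ratio) / length(ratio)
      sds <- c(sds, sqrt(sum((ratio - mu)^2) / (length(ratio) - 1)))
    }
    out[i] <- mean(sds)
  }
  out
}

# pairwise variation by explicit normalization factors
oracle_v <- function(q, stable_order) {
  a <- log2(q[stable_order, , drop = FALSE])
  g <- nrow(a)
  v <- numeric(0)
  for (n in 2:(g - 1)) {
    nf_n <- apply(a[1:n, , drop = FALSE], 2, mean)
    nf_n1 <- apply(a[1:(n + 1), , drop = FALSE], 2, mean)
    d <- nf_n - nf_n1
    v <- c(v, sqrt(sum((d - mean(d))^2) / (length(d) - 1)))
  }
  v
}

# per-sample geometric mean via log-domain accumulation
oracle_index <- function(v) {
  out <- numeric(ncol(v))
  for (s in seq_len(ncol(v))) {
    acc <- 0
    for (g in seq_len(nrow(v))) acc <- acc + log(v[g, s])
    out[s] <- exp(acc / nrow(v))
  }
  names(out) <- colnames(v)
  out
}

# textbook Pearson correlation: covariance over product of SDs
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# competition rank = 1 + number of strictly better values
oracle_comp_rank <- function(values, descending = FALSE) {
  out <- integer(length(values))
  for (i in seq_along(values)) {
    better <- if (descending) sum(values > values[i])
              else sum(values < values[i])
    out[i] <- 1L + better
  }
  names(out) <- names(values)
  out
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# NormFinder pair stability recomputed by loops from the fitted pieces
oracle_pair_stability <- function(nf, g1, g2) {
  K <- length(nf$group_sizes)
  acc <- 0
  for (k in seq_len(K)) {
    dbar <- (nf$shrunken_dev[g1, k] + nf$shrunken_dev[g2, k]) / 2
    se2 <- nf$intragroup_var[g1, k] / nf$group_sizes[k] +
      nf$intragroup_var[g2, k] / nf$group_sizes[k]
    acc <- acc + abs(dbar) + sqrt(se2) / 2
  }
  unname(acc / K)
}
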