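#' Amplification efficiency from a standard-curve slope
#'
#' Converts the slope of a dilution-series standard curve (Cp against log10
#' template amount) into the per-cycle amplification efficiency
#' \deqn{E = 10^{-1/A} - 1,} where \eqn{A} is the slope in cycles per log10
#' unit. \eqn{E = 1} corresponds to perfect doubling (slope
#' \eqn{-1/\log_{10} 2 \approx -3.322}).
#'
#' @param slope_A Standard-curve slope in cycles per log10 template unit;
#'   must be negative (more template, earlier crossing).
#' @param percent_of_doubling If `TRUE`, return the percent-of-doubling form
#'   \eqn{10^{-1/A} \cdot 100} instead (200 = perfect doubling). The fraction
#'   form is the default because it is the one consistent with reported
#'   efficiency tables.
#' @return Efficiency as a fraction (or percent-of-doubling).
#' @examples
#' efficiency_from_slope(-3.322)  # ~1: perfect doubling
#' efficiency_from_slope(-3.482)  # 0.937
#' @export
efficiency_from_slope <- function(slope_A, percent_of_doubling = FALSE) {
  if (any(!is.finite(slope_A)) || any(slope_A >= 0))
    stop("slope must be negative and finite (non-amplifying fit)")
  e <- 10^(-1 / slope_A)
  if (percent_of_doubling) 100 * e else e - 1
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of quantification cycle against log10 template
#' amount for one primer pair: \eqn{Cp = A \log_{10}(amount) + b}. The fit's
#' squared correlation and the amplification efficiency derived from the
#' slope are reported alongside.
#'
#' @param log10_amount Numeric vector of log10 template amounts (>= 3
#'   distinct values).
#' @param cp Quantification cycles, same length.
#' @param gene Optional gene/primer identifier carried into the result.
#' @return Object of class `standard_curve`: list with `gene`, `slope_A`,
#'   `intercept`, `r_squared`, `efficiency_E` (`NA` when the slope is
#'   non-negative), `n`, and the `lm` fit as `fit`.
#' @examples
#' x <- c(0, -1, -2, -3)
#' fit_standard_curve(x, 20 - 1 / log10(2) * x, gene = "actb")
#' @export
fit_standard_curve <- function(log10_amount, cp, gene = NA_character_) {
  x <- as.numeric(log10_amount)
  y <- as.numeric(cp)
  if (length(x) != length(y)) stop("inputs must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 dilution points")
  if (length(unique(x)) < 2)
    stop("all log10 amounts identical; cannot fit a dilution series")
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(y) == 0) 1 else unname(stats::cor(x, y)^2)
  eff <- if (a < 0) efficiency_from_slope(a) else NA_real_
  structure(list(gene = gene, slope_A = a, intercept = b, r_squared = r2,
                 efficiency_E = eff, n = length(x), fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Standard curve", if (!is.na(x$gene)) paste0(" [", x$gene, "]"),
      ": Cp = ", sprintf("%.4f", x$slope_A), " * log10(amount) + ",
      sprintf("%.4f", x$intercept), "\n", sep = "")
  cat(sprintf("  R^2 = %.4f, efficiency E = %s (n = %d)\n", x$r_squared,
              ifelse(is.na(x$efficiency_E), "undefined (slope >= 0)",
                     sprintf("%.4f", x$efficiency_E)), x$n))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope_A = object$slope_A)
}

#' Fit standard curves for a table of dilution series
#'
#' @param d Data frame with columns `gene`, `log10_amount`, `cp`.
#' @return Data frame with one row per gene: `gene`, `r_squared`, `slope_A`,
#'   `efficiency_E`, `n` (columns mirroring a standard assay-performance
#'   table).
#' @export
fit_standard_curves <- function(d) {
  stopifnot(all(c("gene", "log10_amount", "cp") %in% names(d)))
  res <- lapply(split(d, d$gene), function(di) {
    sc <- fit_standard_curve(di$log10_amount, di$cp, gene = di$gene[1])
    data.frame(gene = sc$gene, r_squared = sc$r_squared,
               slope_A = sc$slope_A, efficiency_E = sc$efficiency_E,
               n = sc$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(match(out$gene, unique(d$gene))), , drop = FALSE]
}
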