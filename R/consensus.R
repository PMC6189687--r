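#' Competition ranks ("1224" ranking)
#'
#' Ranks values so that tied items share the minimum rank and the next rank
#' skips by the tie size. Used for every per-method stability ranking and for
#' the final consensus.
#'
#' @param values Named numeric vector (names = genes); all values must be
#'   finite.
#' @param direction `"ascending_better"` (small statistic = rank 1, e.g.
#'   geNorm M) or `"descending_better"` (large statistic = rank 1, e.g.
#'   BestKeeper r).
#' @return Named integer vector of ranks.
#' @examples
#' competition_ranks(c(a = 0.996, b = 0.996, c = 0.994), "descending_better")
#' @export
competition_ranks <- function(values,
                              direction = c("ascending_better",
                                            "descending_better")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values)))
    stop("non-finite value for: ",
         paste(names(values)[!is.finite(values)], collapse = ", "))
  key <- if (direction == "ascending_better") values else -values
  r <- rank(key, ties.method = "min")
  stats::setNames(as.integer(r), names(values))
}

#' Per-method stability table
#'
#' Light container tying a method's per-gene statistic to its competition
#' ranking.
#'
#' @param method Method label (e.g. `"bestkeeper"`).
#' @param statistic Named numeric vector of per-gene statistics. `NA` values
#'   (e.g. an undefined correlation for a zero-variance gene) are flagged and
#'   ranked last.
#' @param direction Rank direction, see [competition_ranks()].
#' @return Data frame of class `stability_table` with columns `gene`,
#'   `statistic`, `rank`; attributes `method` and `direction`.
#' @export
stability_table <- function(method, statistic,
                            direction = c("ascending_better",
                                          "descending_better")) {
  direction <- match.arg(direction)
  ok <- is.finite(statistic)
  rk <- rep.int(NA_integer_, length(statistic))
  if (any(ok)) rk[ok] <- competition_ranks(statistic[ok], direction)
  if (any(!ok)) {
    warning("undefined statistic for ",
            paste(names(statistic)[!ok], collapse = ", "),
            "; ranked last")
    rk[!ok] <- max(rk[ok], 0L) + 1L
  }
  structure(
    data.frame(gene = names(statistic), statistic = unname(statistic),
               rank = rk, stringsAsFactors = FALSE),
    method = method, direction = direction,
    class = c("stability_table", "data.frame"))
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Stability table [", attr(x, "method"), "], ",
      sub("_", " ", attr(x, "direction")), "\n", sep = "")
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Consensus ranking by geometric mean of method ranks
#'
#' Aggregates two or more per-method stability rankings into a comprehensive
#' ranking: each gene's consensus score is the geometric mean of its method
#' ranks, and the final ranking orders genes by ascending score (competition
#' ties).
#'
#' @param tables List of [stability_table()] objects (or data frames with
#'   `gene` and `rank` columns) over an identical gene set.
#' @return Data frame of class `consensus_ranking`: one column of ranks per
#'   method, plus `geo_mean` and `final_rank`, rows ordered as the first
#'   table's genes.
#' @examples
#' a <- stability_table("m1", c(g1 = 0.1, g2 = 0.3, g3 = 0.2))
#' b <- stability_table("m2", c(g1 = 0.99, g2 = 0.90, g3 = 0.95),
#'                      "descending_better")
#' comprehensive_ranking(list(a, b))
#' @export
comprehensive_ranking <- function(tables) {
  if (length(tables) < 2) stop("need >= 2 method tables")
  base <- tables[[1]]$gene
  meth <- vapply(seq_along(tables), function(i) {
    m <- attr(tables[[i]], "method")
    if (is.null(m)) paste0("method", i) else m
  }, character(1))
  rk <- sapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    if (!setequal(t$gene, base))
      stop("gene sets differ between tables: ",
           paste(union(setdiff(t$gene, base), setdiff(base, t$gene)),
                 collapse = ", "))
    t$rank[match(base, t$gene)]
  })
  colnames(rk) <- make.unique(paste0("rank_", meth))
  gm <- exp(rowMeans(log(rk)))
  fin <- competition_ranks(stats::setNames(gm, base), "ascending_better")
  out <- data.frame(gene = base, rk, geo_mean = gm,
                    final_rank = as.integer(fin),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("consensus_ranking", "data.frame"))
}

#' @export
print.consensus_ranking <- function(x, digits = 3, ...) {
  cat("Consensus ranking (geometric mean of",
      sum(startsWith(names(x), "rank_")), "method ranks)\n")
  print.data.frame(x[order(x$final_rank), ], row.names = FALSE,
                   digits = digits)
  invisible(x)
}
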