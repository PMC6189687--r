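test_that("competition ranks share the minimum and skip after ties", {
  expect_equal(competition_ranks(c(a = 0.996, b = 0.996, c = 0.994),
                                 "descending_better"),
               c(a = 1L, b = 1L, c = 3L))
  expect_equal(competition_ranks(c(x = 1, y = 2, z = 3),
                                 "ascending_better"),
               c(x = 1L, y = 2L, z = 3L))
  expect_equal(unname(competition_ranks(rep(5, 4), "ascending_better")),
               rep(1L, 4))
  expect_error(competition_ranks(c(a = 1, b = NA)), "non-finite")
})

test_that("competition ranks agree with the count-of-better oracle", {
  set.seed(53)
  for (i in 1:20) {
    v <- sample(round(runif(9, 0, 5), 1))  # duplicates likely
    names(v) <- paste0("g", 1:9)
    expect_equal(competition_ranks(v, "ascending_better"),
                 oracle_comp_rank(v))
    expect_equal(competition_ranks(v, "descending_better"),
                 oracle_comp_rank(v, descending = TRUE))
    # valid competition ranking: min rank 1, ranks within 1..n
    r <- competition_ranks(v, "ascending_better")
    expect_equal(min(r), 1L)
    expect_true(all(r >= 1 & r <= length(v)))
  }
})

test_that("geometric mean of ranks matches published worked rows", {
  mk <- function(ranks) {
    structure(data.frame(gene = names(ranks), statistic = NA_real_,
                         rank = unname(ranks)),
              method = "m", direction = "ascending_better",
              class = c("stability_table", "data.frame"))
  }
  tabs <- list(mk(c(ywhaz = 1, hprt1 = 5, ubc = 13)),
               mk(c(ywhaz = 1, hprt1 = 1, ubc = 13)),
               mk(c(ywhaz = 9, hprt1 = 10, ubc = 13)),
               mk(c(ywhaz = 3, hprt1 = 2, ubc = 13)))
  cons <- comprehensive_ranking(tabs)
  gm <- setNames(cons$geo_mean, cons$gene)
  expect_equal(gm[["ywhaz"]], 2.28, tolerance = 0.005)
  expect_equal(gm[["hprt1"]], 3.16, tolerance = 0.005)
  expect_equal(gm[["ubc"]], 13, tolerance = 1e-12)
  expect_equal(setNames(cons$final_rank, cons$gene),
               c(ywhaz = 1L, hprt1 = 2L, ubc = 3L))
})

test_that("consensus scores are bounded by their ranks and order-invariant", {
  set.seed(59)
  mk <- function(ranks, meth) {
    structure(data.frame(gene = names(ranks), statistic = NA_real_,
                         rank = unname(ranks)),
              method = meth, direction = "ascending_better",
              class = c("stability_table", "data.frame"))
  }
  g <- paste0("g", 1:8)
  tabs <- lapply(1:4, function(i)
    mk(setNames(sample(8), g), paste0("m", i)))
  cons <- comprehensive_ranking(tabs)
  rk <- as.matrix(cons[startsWith(names(cons), "rank_")])
  expect_true(all(cons$geo_mean >= apply(rk, 1, min) - 1e-12))
  expect_true(all(cons$geo_mean <= apply(rk, 1, max) + 1e-12))
  # permutation invariance across methods
  cons2 <- comprehensive_ranking(tabs[c(3, 1, 4, 2)])
  expect_equal(cons2$geo_mean, cons$geo_mean, tolerance = 1e-12)
  expect_equal(cons2$final_rank, cons$final_rank)
  # final ranking is itself a competition ranking
  expect_equal(setNames(cons$final_rank, cons$gene),
               competition_ranks(setNames(cons$geo_mean, cons$gene),
                                 "ascending_better"))
})

test_that("two identical methods reproduce either method's ranking", {
  st <- stability_table("m", c(a = 0.1, b = 0.3, c = 0.2))
  cons <- comprehensive_ranking(list(st, st))
  expect_equal(cons$final_rank, st$rank)
  expect_equal(cons$geo_mean, st$rank)
})

test_that("gene-set mismatches are rejected with the offending genes named", {
  a <- stability_table("m1", c(g1 = 1, g2 = 2))
  b <- stability_table("m2", c(g1 = 1, g3 = 2))
  expect_error(comprehensive_ranking(list(a, b)), "g3")
  expect_error(comprehensive_ranking(list(a)), ">= 2")
})
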