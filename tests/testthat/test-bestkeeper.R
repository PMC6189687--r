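test_that("descriptive statistics match closed forms", {
  d <- cp_descriptive_stats(c(2, 8), dispersion = "sd")
  expect_equal(d$geo_mean_cp, 4)
  expect_equal(d$ar_mean_cp, 5)
  d2 <- cp_descriptive_stats(rep(22, 6))
  expect_equal(unlist(d2[c("geo_mean_cp", "ar_mean_cp", "min_cp", "max_cp")]),
               c(geo_mean_cp = 22, ar_mean_cp = 22, min_cp = 22,
                 max_cp = 22))
  expect_equal(d2$sd_cp, 0)
  expect_equal(d2$cv_pct, 0)
  expect_error(cp_descriptive_stats(c(-1, 2, 3)), "non-positive")
  # CV% identity holds for either dispersion choice
  x <- c(26.9, 28.2, 27.4, 29.1, 30.3)
  for (disp in c("mad", "sd")) {
    d3 <- cp_descriptive_stats(x, dispersion = disp)
    expect_equal(d3$cv_pct, 100 * d3$sd_cp / d3$ar_mean_cp)
  }
})

test_that("CV% is scale-invariant but not shift-invariant", {
  x <- c(21.2, 22.8, 24.1, 20.9, 23.3)
  base <- cp_descriptive_stats(x)$cv_pct
  expect_equal(cp_descriptive_stats(3.7 * x)$cv_pct, base, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cp_descriptive_stats(x + 5)$cv_pct, base)))
})

test_that("index is the per-sample geometric mean, matching the log oracle", {
  m <- make_cp(rbind(a = c(20, 22, 21), b = c(30, 33, 31)))
  idx <- bestkeeper_index(m)
  expect_equal(unname(idx[1:2]), c(sqrt(20 * 30), sqrt(22 * 33)),
               tolerance = 1e-12)
  expect_equal(unname(bestkeeper_index(m, "a")), unname(m$values["a", ]))
  big <- simulate_cp(sim_config(seed = 17))
  expect_equal(bestkeeper_index(big), oracle_index(big$values),
               tolerance = 1e-12)
  expect_error(bestkeeper_index(m, "zz"), "unknown gene")
})

test_that("correlations with the index match the textbook oracle", {
  m <- simulate_cp(sim_config(seed = 23))
  bk <- bestkeeper(m)
  idx <- bk$index
  for (g in genes(m))
    expect_equal(bk$table$pearson_r[bk$table$gene == g],
                 oracle_pearson(m$values[g, ], idx), tolerance = 1e-10)
  expect_true(all(abs(bk$table$pearson_r) <= 1))
})

test_that("identical rows give r = 1; affine latent structure gives |r| near 1", {
  v <- matrix(rep(c(20, 21.5, 23, 19.5, 22), each = 3), nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:5)))
  bk <- bestkeeper(make_cp(v, timepoint_h = c(0, 12, 24, 48, 72)))
  expect_equal(bk$table$pearson_r, rep(1, 3), tolerance = 1e-12)
  expect_true(all(bk$table$rank == 1))

  u <- c(0, 0.4, 0.9, 1.3, 1.8, 2.2)  # latent sample effect
  v2 <- rbind(a = 21 + u, b = 23 + 2 * u, c = 26 - u)
  colnames(v2) <- paste0("s", 1:6)
  bk2 <- bestkeeper(make_cp(v2, timepoint_h = c(0, 12, 24, 36, 48, 72)))
  r <- setNames(bk2$table$pearson_r, bk2$table$gene)
  expect_gt(r[["a"]], 0.999)
  expect_gt(r[["b"]], 0.999)
  expect_lt(r[["c"]], -0.999)  # anti-correlated gene is unstable, ranked last
  expect_equal(bk2$table$rank[bk2$table$gene == "c"], 3)
})

test_that("zero-variance genes are flagged and ranked last", {
  v <- rbind(a = c(20, 21, 22, 23), b = c(25, 26, 27, 28),
             flat = rep(24, 4))
  colnames(v) <- paste0("s", 1:4)
  expect_warning(bk <- bestkeeper(make_cp(v, timepoint_h = c(0, 12, 24, 48))),
                 "ranked last")
  expect_true(is.na(bk$table$pearson_r[bk$table$gene == "flat"]))
  expect_equal(max(bk$table$rank), bk$table$rank[bk$table$gene == "flat"])
})

test_that("ranking by correlation is a competition ranking", {
  r <- c(g1 = 0.996, g2 = 0.996, g3 = 0.994, g4 = 0.992, g5 = 0.99,
         g6 = 0.99, g7 = 0.984)
  st <- stability_table("bestkeeper", r, "descending_better")
  expect_equal(st$rank, c(1L, 1L, 3L, 4L, 5L, 5L, 7L))
})
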