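test_that("Cp table round-trips through write and read", {
  m <- simulate_cp(sim_config(seed = 101))
  tab <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  write_cp_table(m, tab, sheet)
  m2 <- read_cp_table(tab, sheet)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(rownames(m2$values), rownames(m$values))
  expect_equal(m2$samples$timepoint_h, m$samples$timepoint_h)
  expect_equal(m2$samples$group, m$samples$group)
})

test_that("reader turns missing markers into NA and rejects bad input", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3",
               "g1\t20.1\tUndetermined\t21.0",
               "g2\t25.0\t\t24.5"), tab)
  writeLines(c("sample_id\tgroup\ttimepoint_h\treplicate",
               "s1\tcontrol\t0\t1", "s2\ttreated\t24\t1",
               "s3\ttreated\t48\t1"), sheet)
  m <- read_cp_table(tab, sheet)
  expect_true(is.na(m$values["g1", "s2"]))
  expect_true(is.na(m$values["g2", "s2"]))
  expect_equal(m$values["g1", "s1"], 20.1)

  # a column absent from the sample sheet is a contract violation
  writeLines(c("sample_id\tgroup\ttimepoint_h\treplicate",
               "s1\tcontrol\t0\t1", "s2\ttreated\t24\t1"), sheet)
  expect_error(read_cp_table(tab, sheet), "absent from sample sheet")

  # non-numeric cells are named in the error
  writeLines(c("gene\ts1\ts2\ts3", "g1\t20.1\toops\t21.0"), tab)
  writeLines(c("sample_id\tgroup\ttimepoint_h\treplicate",
               "s1\tcontrol\t0\t1", "s2\ttreated\t24\t1",
               "s3\ttreated\t48\t1"), sheet)
  expect_error(read_cp_table(tab, sheet), "oops.*g1.*s2")
})

test_that("cp_matrix validation catches structural violations", {
  v <- matrix(20, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  s <- data.frame(sample_id = c("s1", "s2"), group = "control",
                  timepoint_h = 0, replicate = 1)
  expect_error(cp_matrix(v, s), "duplicate gene")
  v2 <- matrix(c(20, -1, 21, 22), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(cp_matrix(v2, s), "non-positive Cp")
  expect_error(cp_matrix(v2[, 1, drop = FALSE], s), "sample sheet")
})

test_that("Cp range filter excludes by mean and missingness, strictly", {
  tp <- rep(c(0, 12, 24, 36, 48, 72), each = 2)
  v <- rbind(
    low_expr  = rep(30.4, 12),       # mean above 30: out
    constant  = rep(22, 12),         # in
    boundary  = rep(30, 12),         # exactly 30: retained (strict)
    early     = rep(14.2, 12),       # below 15: out
    dropout   = c(rep(25, 11), NA))  # missing in treated: out
  colnames(v) <- paste0("s", 1:12)
  m <- make_cp(v, timepoint_h = tp)
  f <- filter_genes_by_cp_range(m)
  expect_setequal(genes(f$matrix), c("constant", "boundary"))
  rep <- f$report
  expect_setequal(rep$gene, rownames(v))
  expect_equal(rep$statistic[rep$gene == "low_expr"], 30.4)
  expect_match(rep$reason[rep$gene == "dropout"], "missing")
  # retained and excluded partition the input
  expect_length(intersect(genes(f$matrix),
                          rep$gene[rep$status == "excluded"]), 0)

  # idempotent: a second pass removes nothing
  f2 <- filter_genes_by_cp_range(f$matrix)
  expect_identical(genes(f2$matrix), genes(f$matrix))

  # one low-expressed gene among a realistic panel: 13 of 14 remain
  m14 <- simulate_cp(sim_config(seed = 9))
  v14 <- rbind(m14$values, eef1a1 = rep(30.4, ncol(m14$values)))
  f14 <- filter_genes_by_cp_range(cp_matrix(v14, m14$samples))
  expect_equal(nrow(f14$matrix$values), 13)
  expect_false("eef1a1" %in% genes(f14$matrix))

  expect_error(filter_genes_by_cp_range(make_cp(rbind(g = rep(35, 12)),
                                                timepoint_h = tp)),
               "all genes excluded")
})

test_that("split_groups partitions samples under each scheme", {
  m <- simulate_cp(sim_config(seed = 5))
  g <- split_groups(m, "control_vs_treated")
  expect_equal(lengths(g)[["control"]], 3)
  expect_equal(lengths(g)[["treated"]], 15)
  g2 <- split_groups(m, "by_timepoint")
  expect_length(g2, 6)
  expect_true(all(lengths(g2) == 3))
  for (gr in list(g, g2))
    expect_identical(sort(unlist(gr, use.names = FALSE)), 1:18)
  one_tp <- make_cp(matrix(20, 3, 4,
                           dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:4))),
                    timepoint_h = rep(24, 4))
  expect_error(split_groups(one_tp, "by_timepoint"), ">= 2 groups")
})
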