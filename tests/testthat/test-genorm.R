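test_that("relative quantities are powers of 1+E below each gene's min Cp", {
  q <- to_relative_quantities(rbind(g = c(s1 = 20, s2 = 21, s3 = 23)))
  expect_equal(unname(q["g", ]), c(1, 0.5, 0.125))
  qc <- to_relative_quantities(rbind(g = c(s1 = 22, s2 = 22, s3 = 22)))
  expect_equal(unname(qc["g", ]), c(1, 1, 1))
  # efficiency-corrected: dCp of 1 at E = 0.937, against a log-domain oracle
  q2 <- to_relative_quantities(rbind(g = c(s1 = 20, s2 = 21, s3 = 22)),
                               efficiency = 0.937)
  expect_equal(unname(q2["g", 2]), 1 / 1.937, tolerance = 1e-12)
  expect_equal(log(unname(q2["g", ])), -(0:2) * log(1.937),
               tolerance = 1e-12)
  expect_error(to_relative_quantities(rbind(g = c(20, NA, 21))), "missing")
})

test_that("M is zero for proportional genes and matches the pairwise oracle", {
  # Cp rows differing by a constant = proportional quantities
  m <- make_cp(rbind(a = c(20, 21, 23, 24), b = c(25, 26, 28, 29)),
               timepoint_h = c(0, 12, 24, 48))
  expect_equal(unname(genorm_m(m)), c(0, 0), tolerance = 1e-12)

  # an exactly duplicated gene contributes zero to its twin's M
  v3 <- rbind(a = c(20, 21, 23, 24), a2 = c(20, 21, 23, 24),
              c = c(22, 24, 25, 29))
  colnames(v3) <- paste0("s", 1:4)
  m3 <- genorm_m(make_cp(v3, timepoint_h = c(0, 12, 24, 48)))
  expect_equal(m3[["a"]], m3[["a2"]], tolerance = 1e-12)
  expect_lt(m3[["a"]], m3[["c"]])

  q <- to_relative_quantities(rand_cp(5, 12, seed = 31))
  expect_equal(genorm_m(q), oracle_m(q), tolerance = 1e-10)
  expect_true(all(genorm_m(q) >= 0))
})

test_that("M is invariant to per-gene constant Cp shifts", {
  for (s in 1:5) {
    m <- rand_cp(5, 10, seed = 100 + s)
    shift <- m$values
    shift[2, ] <- shift[2, ] + 3.7
    expect_equal(genorm_m(to_relative_quantities(m$values)),
                 genorm_m(to_relative_quantities(shift)),
                 tolerance = 1e-10)
  }
})

test_that("independent noise on one gene increases its M", {
  worse <- 0
  for (s in 1:100) {
    set.seed(4000 + s)
    base <- matrix(20 + rnorm(5 * 8, 0, 0.1), 5, 8,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    noisy <- base
    noisy[1, ] <- noisy[1, ] + rnorm(8, 0, 0.8)
    m0 <- genorm_m(to_relative_quantities(base))[["g1"]]
    m1 <- genorm_m(to_relative_quantities(noisy))[["g1"]]
    if (m1 > m0) worse <- worse + 1
  }
  expect_gte(worse, 95)
})

test_that("stepwise exclusion removes the noisy gene first", {
  hit <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    v <- rbind(clean1 = 22 + rnorm(8, 0, 0.05),
               clean2 = 24 + rnorm(8, 0, 0.05),
               noisy = 23 + rnorm(8, 0, 1))
    colnames(v) <- paste0("s", 1:8)
    gn <- suppressWarnings(
      genorm(make_cp(v, timepoint_h = rep(c(0, 24, 48, 72), 2))))
    if (gn$exclusion_order[1] == "noisy") hit <- hit + 1
  }
  expect_gte(hit, 19)
})

test_that("ties at removal fall to the later gene and are logged", {
  v <- rbind(a = c(20, 21, 23, 24), b = c(25, 26, 28, 29),
             c = c(21, 22, 24, 25))  # all proportional: all M = 0
  colnames(v) <- paste0("s", 1:4)
  gn <- genorm(make_cp(v, timepoint_h = c(0, 12, 24, 48)))
  expect_equal(max(gn$m_values), 0, tolerance = 1e-12)
  expect_equal(gn$exclusion_order, "c")
  expect_equal(nrow(gn$ties), 1)
})

test_that("full-panel run has the expected structure and shared top rank", {
  gn <- genorm(simulate_cp(sim_config(seed = 13)))
  expect_length(gn$exclusion_order, 11)
  expect_length(gn$final_pair, 2)
  rk <- setNames(gn$ranking$rank, gn$ranking$gene)
  expect_equal(unname(sort(rk)[1:3]), c(1, 1, 3))  # pair shares rank 1
  expect_setequal(names(rk)[rk == 1], gn$final_pair)
  # removal is idempotent: rerunning on the survivors of the first step
  # reproduces the remaining exclusion order
  sub <- genorm(simulate_cp(sim_config(seed = 13))[
    setdiff(gn$ranking$gene, gn$exclusion_order[1]), ])
  expect_equal(sub$exclusion_order, gn$exclusion_order[-1])
  expect_setequal(sub$final_pair, gn$final_pair)
})

test_that("pairwise variation matches its brute-force oracle", {
  m <- make_cp(matrix(rep(c(20, 21, 23, 22), each = 4), nrow = 4,
                      dimnames = list(paste0("g", 1:4), paste0("s", 1:4))),
               timepoint_h = c(0, 12, 24, 48))
  gn <- genorm(m)
  expect_equal(gn$v_curve$v, rep(0, 2), tolerance = 1e-12)

  q <- to_relative_quantities(rand_cp(6, 12, seed = 77))
  ord <- rownames(q)
  expect_equal(pairwise_variation(q, ord)$v, oracle_v(q, ord),
               tolerance = 1e-10)
})

test_that("optimal gene count follows the V cutoff", {
  expect_equal(optimal_gene_count(data.frame(n = 2:3, v = c(0.09, 0.12))), 2)
  expect_equal(optimal_gene_count(data.frame(n = 2:3, v = c(0.20, 0.14))), 3)
  expect_warning(
    g <- optimal_gene_count(data.frame(n = 2:4, v = c(0.3, 0.2, 0.19))),
    "no V")
  expect_equal(g, 5)
})
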