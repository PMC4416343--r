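ssri <- c(fluoxetine = 4.25, fluvoxamine = 3.85, sertraline = 3.68,
          citalopram = 3.57, paroxetine = 3.77, escitalopram = 3.57)

test_that("the constrained split reproduces the SSRI sexual-dysfunction partition", {
  sp <- split_two(unname(ssri))
  expect_equal(sp$n_clusters, 2L)
  expect_setequal(names(ssri)[sp$assignment == 2L],
                  c("fluoxetine", "fluvoxamine"))
  expect_setequal(names(ssri)[sp$assignment == 1L],
                  c("sertraline", "citalopram", "paroxetine", "escitalopram"))
})

test_that("split_two handles clean separations and degenerate inputs", {
  sp <- split_two(c(1, 2, 9, 10))
  expect_equal(sp$assignment, c(1L, 1L, 2L, 2L))
  expect_equal(split_two(c(3, 3, 3, 3))$n_clusters, 1L)
  expect_equal(split_two(c(3, 3, 3, 3))$degenerate, FALSE)
  short <- split_two(c(1, 2, 9))
  expect_equal(short$n_clusters, 1L)
  expect_true(short$degenerate)
})

test_that("split_two equals exhaustive search over all 2-partitions (size >= 2)", {
  set.seed(42)
  grid <- c(-5, -1, -0.2, 0, 0.1, 0.5, 1, 2, 3.5, 7)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    v <- sample(grid, n, replace = TRUE)
    sp <- split_two(v)
    if (sp$n_clusters == 1L) {
      expect_lt(length(unique(v)), 2L)
      next
    }
    expect_equal(within_ss(v, sp$assignment), bf_best_partition_ss(v),
                 tolerance = 1e-12)
  }
})

test_that("welch_test matches the closed-form statistic and its degenerate cases", {
  got <- welch_test(c(1, 2, 3), c(7, 8, 9))
  oracle <- bf_welch(c(1, 2, 3), c(7, 8, 9))
  expect_equal(abs(got$t_stat), 7.348, tolerance = 1e-3)
  expect_equal(got$dof, 4, tolerance = 1e-9)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(round(got$p_value, 4), 0.0018)

  same <- welch_test(c(1, 2), c(1, 2))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  # zero variance in both groups
  expect_equal(welch_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_test(c(2, 2), c(3, 3))$p_value, 0)
  expect_error(welch_test(1, c(1, 2)), "at least 2")

  # symmetry: swapping groups flips t, keeps p and dof
  a <- rnorm(4); b <- rnorm(5) + 1
  f <- welch_test(a, b); r <- welch_test(b, a)
  expect_equal(f$t_stat, -r$t_stat)
  expect_equal(f$p_value, r$p_value)
  expect_equal(f$dof, r$dof)
})

test_that("welch_test agrees with the closed form across random inputs", {
  set.seed(7)
  for (rep in 1:25) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), sd = 2)
    got <- welch_test(a, b)
    oracle <- bf_welch(a, b)
    expect_equal(got$t_stat, oracle$t, tolerance = 1e-10)
    expect_equal(got$dof, oracle$dof, tolerance = 1e-10)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("the SSRI worked example is classified as a class effect", {
  res <- classify_pair("N06AB", "sexual_dysfunctions", ssri)
  expect_equal(res$n_clusters, 2L)
  expect_equal(round(res$p_value, 2), 0.28)
  expect_equal(res$verdict, "class_effect_homogeneous")
  expect_setequal(res$partition[[2L]], c("fluoxetine", "fluvoxamine"))
})

test_that("verdicts cover single-cluster, homogeneous and heterogeneous cases", {
  const <- classify_pair("C", "E", c(m1 = 2, m2 = 2, m3 = 2, m4 = 2))
  expect_equal(const$verdict, "class_effect_single_cluster")
  expect_equal(const$n_clusters, 1L)
  expect_true(is.na(const$p_value))

  het <- classify_pair("C", "E",
                       c(a = 3.0, b = 3.0, c = 0.1, d = 0.1, e = 0.1,
                         f = 0.05))
  expect_equal(het$verdict, "heterogeneous")
  expect_lt(het$p_value, 0.05)
  expect_setequal(het$partition[[2L]], c("a", "b"))
})

test_that("verdicts are invariant under a constant shift of all log-PRRs", {
  set.seed(11)
  for (rep in 1:20) {
    v <- setNames(rnorm(6), paste0("m", 1:6))
    base <- classify_pair("C", "E", v)
    shifted <- classify_pair("C", "E", v + 2.7)
    expect_equal(shifted$verdict, base$verdict)
    expect_equal(shifted$p_value, base$p_value, tolerance = 1e-9)
    expect_identical(shifted$partition, base$partition)
  }
})

test_that("the Lloyd k-means mode agrees with the deterministic split on separated data", {
  set.seed(5)
  v <- setNames(c(rnorm(3, 0, 0.05), rnorm(3, 5, 0.05)), paste0("m", 1:6))
  km <- classify_pair("C", "E", v, method = "kmeans")
  opt <- classify_pair("C", "E", v, method = "optimal")
  expect_equal(canon_partition(km$partition), canon_partition(opt$partition))
})

test_that("pair eligibility requires evidence for every class member", {
  drug_recs <- data.frame(
    level = "drug_x_ade_class",
    row_id = c("d1", "d2", "d3", "d4", "d1", "d2", "d3", "d1"),
    col_id = c("E1", "E1", "E1", "E1", "E2", "E2", "E2", "E3"),
    a = 1, b = 1, c = 1, d = 1, corrected = FALSE, prr = 2,
    log_prr = log(2), stringsAsFactors = FALSE)
  members <- list(CL = c("d1", "d2", "d3", "d4"))
  el <- eligible_pairs(members, drug_recs)
  # E1 covered by all 4 members; E2 by 3 of 4; E3 by 1 of 4
  expect_equal(el$ade_id, "E1")
  # fluoroquinolone-style case: 14 members, only 4 with data -> excluded
  fq <- list(FQ = sprintf("f%02d", 1:14))
  fq_recs <- drug_recs[1:4, ]
  fq_recs$row_id <- sprintf("f%02d", 1:4)
  expect_equal(nrow(eligible_pairs(fq, fq_recs)), 0L)
})

test_that("class_effect_scan emits one verdict row per eligible pair", {
  empty <- eligible_pairs(list(), data.frame(row_id = character(),
                                             col_id = character(),
                                             log_prr = numeric()))
  expect_equal(nrow(class_effect_scan(empty, data.frame(row_id = character(),
                                                        col_id = character(),
                                                        log_prr = numeric()),
                                      list())), 0L)

  set.seed(21)
  drug_recs <- expand.grid(row_id = paste0("d", 1:6), col_id = c("E1", "E2"),
                           stringsAsFactors = FALSE)
  drug_recs$log_prr <- rnorm(nrow(drug_recs))
  members <- list(CL = paste0("d", 1:6))
  el <- eligible_pairs(members, drug_recs)
  out <- class_effect_scan(el, drug_recs, members)
  expect_equal(nrow(out), nrow(el))
  expect_true(all(out$verdict %in% c("class_effect_single_cluster",
                                     "class_effect_homogeneous",
                                     "heterogeneous")))
  # verdict rule: two clusters are a class effect iff p > alpha
  two <- out[out$n_clusters == 2L, ]
  expect_equal(two$verdict == "class_effect_homogeneous", two$p_value > 0.05)
})
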