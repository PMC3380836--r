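test_that("p_distance hand cases: mismatch fraction and pairwise deletion", {
  expect_equal(p_distance("ACDE", "ACDF"), list(distance = 0.25, sites = 4L))
  expect_equal(p_distance("AC-EF", "ACDEF"), list(distance = 0, sites = 4L))
  expect_equal(p_distance("ACDE", "ACDE"), list(distance = 0, sites = 4L))
  expect_equal(p_distance("AXDE", "ACDE")$sites, 3L)  # X excluded
  expect_true(is.na(p_distance("----", "ACDE")$distance))
  expect_error(p_distance("ACD", "AC"), "length")
})

test_that("p_distance agrees with a per-position oracle and is metric-like", {
  set.seed(3)
  for (i in 1:40) {
    L <- sample(5:30, 1)
    a <- random_protein(L, x_frac = 0.1)
    b <- random_protein(L, x_frac = 0.1)
    # sprinkle gaps
    a <- sub("A", "-", a); b <- sub("C", "-", b)
    got <- p_distance(a, b)
    want <- oracle_p_distance(a, b)
    expect_equal(got, want)
    expect_equal(p_distance(b, a), got)           # symmetry
    if (!is.na(got$distance)) {
      expect_gte(got$distance, 0); expect_lte(got$distance, 1)
    }
  }
})

test_that("distance_matrix fills all pairs and reports the overall mean", {
  dm0 <- distance_matrix(c(a = "ACDE", b = "ACDE", c = "ACDE"))
  expect_true(all(dm0$distance == 0))
  expect_equal(dm0$overall_mean, 0)

  dm <- distance_matrix(c(a = "AAAA", b = "AAAT", c = "TTTT"))
  expect_equal(dm$distance["a", "b"], 0.25)
  expect_equal(dm$distance["a", "c"], 1)
  expect_equal(dm$distance["b", "c"], 0.75)
  expect_equal(dm$overall_mean, 2 / 3)
  expect_equal(dm$distance, t(dm$distance))

  td <- tidy(dm)
  expect_equal(nrow(td), 3L)
  expect_equal(td$sites, c(4L, 4L, 4L))
})

test_that("distances on a column subset equal distances on the sub-alignment", {
  set.seed(9)
  rows <- vapply(1:4, function(i) random_protein(30, x_frac = 0.05), "")
  names(rows) <- paste0("s", 1:4)
  cols <- sort(sample(30, 12))
  dm_sub <- distance_matrix(rows, columns = cols)
  sub_rows <- vapply(rows, function(r)
    paste(strsplit(r, "")[[1]][cols], collapse = ""), "")
  dm_direct <- distance_matrix(sub_rows)
  expect_equal(dm_sub$distance, dm_direct$distance)
  expect_equal(dm_sub$sites, dm_direct$sites)
  expect_true(all(dm_sub$sites[upper.tri(dm_sub$sites)] <=
                    distance_matrix(rows)$sites[upper.tri(dm_sub$sites)]))
})

test_that("bootstrap variance is deterministic, zero for identical rows, and near theory", {
  aln <- c(a = "AAAA", b = "AAAT")
  v1 <- bootstrap_variance(aln, c("a", "b"), replicates = 500, seed = 3)
  v2 <- bootstrap_variance(aln, c("a", "b"), replicates = 500, seed = 3)
  expect_identical(v1, v2)

  same <- bootstrap_variance(c(a = "ACDE", b = "ACDE"), c("a", "b"),
                             replicates = 100, seed = 1)
  expect_equal(same$variance, 0)

  # resampled mismatch proportion over 4 columns: binomial variance p(1-p)/n
  vb <- bootstrap_variance(aln, c("a", "b"), replicates = 10000, seed = 3)
  theory <- 0.25 * 0.75 / 4
  se <- sqrt(2 / (10000 - 1)) * theory  # SE of a sample variance, normal approx
  expect_lt(abs(vb$variance - theory), 3 * max(se, 0.05 * theory))
})

test_that("partition_columns applies the column-vote rule", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  all_dis <- tibble::tibble(seq_id = c("a", "b", "c", "d"), start = 1L, end = 4L,
                            kind = "disordered")
  p <- partition_columns(aln, all_dis)
  expect_true(all(p$partition == "disordered"))

  none <- all_dis[0, ]
  p2 <- partition_columns(aln, none)
  expect_true(all(p2$partition == "structured"))

  # one column, 3 of 4 rows annotated -> disordered at rule_frac 0.5
  one_col <- tibble::tibble(seq_id = c("a", "b", "c"), start = 2L, end = 2L,
                            kind = "disordered")
  p3 <- partition_columns(aln, one_col, rule_frac = 0.5)
  expect_equal(p3$partition, c("structured", "disordered", "structured", "structured"))

  expect_error(partition_columns(aln, tibble::tibble(seq_id = "zz", start = 1L,
                                                     end = 1L, kind = "disordered")),
               "unknown")
})

test_that("kruskal_wallis reproduces hand-evaluated statistics", {
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p.value, stats::pchisq(7.2, 2, lower.tail = FALSE))

  kw2 <- kruskal_wallis(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(kw2$statistic, 0)
  expect_equal(kw2$tie_correction, 0.8)

  kw3 <- kruskal_wallis(list(a = rep(5, 3), b = rep(5, 3)))
  expect_equal(kw3$statistic, 0)
  expect_equal(kw3$p.value, 1)

  expect_error(kruskal_wallis(list(a = 1:3)), "two groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric())), "non-empty|two groups")
})

test_that("kruskal_wallis takes data frames and matches the rank-formula oracle", {
  df <- data.frame(v = c(1:3, 4:6, 7:9), g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(df, v, g)
  expect_equal(kw$statistic, 7.2)

  set.seed(2)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:8, sample(2:6, 1), replace = TRUE))
    names(groups) <- letters[seq_len(k)]
    got <- kruskal_wallis(groups)
    expect_equal(got$statistic, oracle_kw_h(groups), tolerance = 1e-10)
  }
})

test_that("permutation p-value is seeded and sane", {
  g <- list(a = c(1, 5, 3), b = c(8, 9, 12))
  p1 <- kruskal_wallis(g, p_method = "permutation", n_perm = 500, seed = 4)
  p2 <- kruskal_wallis(g, p_method = "permutation", n_perm = 500, seed = 4)
  expect_equal(p1$p.value, p2$p.value)
  expect_gt(p1$p.value, 0); expect_lt(p1$p.value, 1)
})

test_that("compare_partitions: conserved block gives zero divergence and H = 0", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDEFGHIKL")
  ann <- tibble::tibble(seq_id = c("a", "b", "c"), start = 1L, end = 4L,
                        kind = "disordered")
  cmp <- compare_partitions(aln, ann)
  expect_true(all(cmp$distances$distance == 0))
  expect_equal(cmp$kw$statistic, 0)
  expect_equal(sort(cmp$summary$partition),
               sort(c("full-length", "structured", "disordered")))
})

test_that("randomised disordered columns push their median toward 0.95", {
  set.seed(21)
  n <- 6; L_s <- 120; L_d <- 150
  structured <- random_protein(L_s, x_frac = 0)
  rows <- vapply(seq_len(n), function(i)
    paste0(structured, random_protein(L_d, x_frac = 0)), "")
  names(rows) <- paste0("s", seq_len(n))
  ann <- tibble::tibble(seq_id = names(rows), start = L_s + 1L,
                        end = L_s + L_d, kind = "disordered")
  cmp <- compare_partitions(rows, ann)
  med <- setNames(cmp$summary$median, cmp$summary$partition)
  expect_equal(unname(med["disordered"]), 0.95, tolerance = 0.035)
  expect_equal(unname(med["structured"]), 0)
  expect_lt(cmp$kw$p.value, 0.01)
})

test_that("an empty partition is flagged and KW still runs on the rest", {
  aln <- c(a = "ACDE", b = "ACDF", c = "AGDE")
  expect_warning(cmp <- compare_partitions(aln, tibble::tibble(
    seq_id = character(), start = integer(), end = integer(), kind = character())),
    "empty partition")
  expect_equal(cmp$empty_partitions, "disordered")
  expect_equal(cmp$kw$df, 1L)
})

test_that("the per-row-mask variant agrees with column voting on clean block structure", {
  sim <- simulate_family(simulation_config(taxa = 5, id_length = c(80, 120),
                                           indel_rate = 0), seed = 12)
  ann <- sim$truth$id_regions
  c1 <- compare_partitions(sim$alignment, ann, method = "columns")
  c2 <- compare_partitions(sim$alignment, ann, method = "per-row-mask")
  m1 <- setNames(c1$summary$median, c1$summary$partition)
  m2 <- setNames(c2$summary$median, c2$summary$partition)
  expect_equal(m1[["structured"]], m2[["structured"]], tolerance = 1e-9)
  expect_equal(m1[["disordered"]], m2[["disordered"]], tolerance = 1e-9)
})
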