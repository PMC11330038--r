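test_that("group summaries match a sort-based quantile oracle", {
  s <- summarize_groups(c(1, 2, 3, 4, 5), rep("g", 5))
  expect_equal(s$median, 3)
  s2 <- summarize_groups(rep(7, 10), rep("g", 10))
  expect_equal(s2$q3 - s2$q1, 0)

  set.seed(31)
  v <- rnorm(101)
  s3 <- summarize_groups(v, rep("g", 101))
  sv <- sort(v)
  expect_equal(s3$median, sv[51])       # odd n: middle order statistic
  expect_equal(s3$q1, unname(quantile(v, 0.25, type = 7)))

  s4 <- summarize_groups(c(1, 2, 3, 10), rep("g", 4), type = "mean_sd")
  expect_equal(s4$mean, 4)
  expect_equal(s4$mean_plus_sd - s4$mean, sd(c(1, 2, 3, 10)))

  s5 <- summarize_groups(c(1, NA), factor(c("a", "b"), levels = c("a", "b")))
  expect_equal(s5$n, c(1L, 0L))
  expect_true(is.na(s5$median[2]))
})

test_that("Kruskal-Wallis H matches closed-form rank arithmetic", {
  # {1,2} vs {3,4}: R1 = 3, R2 = 7, N = 4 -> H = 2.4
  r <- kruskal_wallis(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(r$statistic, 2.4)
  expect_equal(r$df, 1)

  ident <- kruskal_wallis(list(a = c(5, 5), b = c(5, 5, 5)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # invariance to within-group permutation and monotone transforms
  set.seed(17)
  g <- list(a = rnorm(8), b = rnorm(9, 1), c = rnorm(7))
  h0 <- kruskal_wallis(g)$statistic
  g_perm <- lapply(g, sample)
  expect_equal(kruskal_wallis(g_perm)$statistic, h0)
  g_mono <- lapply(g, function(v) exp(v) + 2)
  expect_equal(kruskal_wallis(g_mono)$statistic, h0)

  expect_error(kruskal_wallis(list(a = 1)), "two")
})

test_that("Dunn post-hoc matches hand-computed pooled-rank z values", {
  # groups {1,2}, {3,4}, {5,6}: mean ranks 1.5/3.5/5.5, var core 3.5
  d <- dunn_posthoc(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(d$statistic,
               c(-1.069044968, -2.138089935, -1.069044968),
               tolerance = 1e-9)
  expect_equal(d$p_value,
               c(0.2850494074, 0.0325094446, 0.2850494074),
               tolerance = 1e-8)
  # Bonferroni for 3 groups: adjusted = min(1, 3p)
  expect_equal(d$adjusted_p, pmin(1, 3 * d$p_value))

  ident <- dunn_posthoc(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_true(all(ident$statistic == 0))
  expect_true(all(ident$adjusted_p == 1))

  expect_message(
    d2 <- dunn_posthoc(list(a = c(1, 2), b = numeric(), c = c(3, 4),
                            d = c(5, 6))),
    "empty")
  expect_equal(nrow(d2), 3L)
  expect_true(all(d2$adjusted_p >= d2$p_value))
  expect_true(all(d2$adjusted_p <= 1))
})

test_that("Wilcoxon rank-sum exact path equals full enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact enumeration")

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_match(same$method, "approximation")

  set.seed(23)
  for (na in 2:5) for (nb in 2:5) {
    a <- sample(seq_len(100), na)
    b <- setdiff(sample(seq_len(100), na + nb), a)[seq_len(nb)]
    got <- wilcoxon_rank_sum(a, b)
    expect_equal(got$p_value, enumerate_ranksum_p(a, b), tolerance = 1e-10,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("categorical tests pick chi-square or Fisher by expected counts", {
  uniform <- matrix(c(5, 5, 5, 5), 2)
  r <- categorical_test(uniform)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_match(r$method, "chi-square")

  big <- matrix(c(10, 10, 10, 10), 2)
  expect_match(categorical_test(big)$method, "chi-square")
  sparse <- matrix(c(2, 8, 7, 3), 2)
  expect_match(categorical_test(sparse)$method, "fisher")

  # Fisher p equals the hypergeometric tail oracle on random 2x2 tables
  set.seed(29)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- categorical_test(tab, method = "fisher")
    expect_equal(got$p_value, fisher_2x2_oracle(tab), tolerance = 1e-7)
  }

  expect_message(categorical_test(matrix(c(5, 0, 3, 4, 0, 6), 3)),
                 "zero-margin")
  expect_error(categorical_test(matrix(c(3, 0, 4, 0), 2)), "2 x 2")
})

test_that("one-way ANOVA matches closed-form sums of squares", {
  # {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$statistic, 13.5)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pf(13.5, 1, 4, lower.tail = FALSE))

  ident <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  degen <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(degen$statistic, Inf)
  expect_equal(degen$p_value, 0)

  shifted <- one_way_anova(list(a = c(1, 2, 3) + 10, b = c(4, 5, 6) + 10))
  expect_equal(shifted$statistic, 13.5)

  expect_error(one_way_anova(list(a = 1, b = c(2, 3))), ">= 2")
})

test_that("the analysis battery reproduces the published analysis shape", {
  groups <- data.frame(label = c("No", "Low", "Int", "High"),
                       n_cases = 20,
                       gm_diffuse = c(0, 3.75e-7, 5.03e-6, 7.625e-6),
                       gm_cored = c(0, 2.5e-8, 1.21e-6, 1.01e-6))
  cohort <- simulate_cohort(cohort_sim_spec(groups, seed = 11))
  battery <- run_analysis_battery(cohort, "group",
                                  c("density_gm_diffuse", "density_gm_cored"))
  res <- battery$results
  omnibus <- res[res$test == "kruskal_wallis", ]
  expect_equal(nrow(omnibus), 2L)
  # strong group effect: post-hoc rows follow each significant omnibus
  expect_true(all(omnibus$p_value < 0.05))
  expect_equal(sum(res$test == "dunn"), 2 * choose(4, 2))
  expect_true(all(res$adjusted_p[res$test == "dunn"] >=
                  res$p_value[res$test == "dunn"] - 1e-15))

  # two-group plans use the rank-sum test
  two <- cohort[cohort$group %in% c("No", "High"), ]
  b2 <- run_analysis_battery(two, "group", "density_gm_diffuse")
  expect_equal(b2$results$test, "wilcoxon_rank_sum")

  # deferred-diagnosis cases are excluded from the grouping analysis
  cohort$mra <- rep(c("demented", "MCI", "not_demented", "deferred"),
                    length.out = nrow(cohort))
  b3 <- run_analysis_battery(cohort, "mra", "density_gm_diffuse",
                             exclude_levels = "deferred")
  expect_false(any(grepl("deferred", b3$results$comparison)))
  expect_equal(sum(b3$summaries$density_gm_diffuse$group == "deferred"), 0)

  # degenerate grouping is skipped with a notice
  cohort$one <- "all"
  expect_message(
    b4 <- run_analysis_battery(cohort, "one", "density_gm_diffuse"),
    "skipped")
  expect_equal(nrow(b4$results), 0L)
})

test_that("battery reports are written and agree with the results table", {
  groups <- data.frame(label = c("a", "b", "c"), n_cases = 10,
                       gm_diffuse = c(1e-6, 1e-6, 1e-5))
  cohort <- simulate_cohort(cohort_sim_spec(groups, seed = 3))
  battery <- run_analysis_battery(cohort, "group", "density_gm_diffuse")
  dir <- withr::local_tempdir()
  write_battery_report(battery, dir, "demo")
  res_csv <- read.csv(file.path(dir, "demo_results.csv"))
  expect_equal(nrow(res_csv), nrow(battery$results))
  expect_equal(res_csv$p_value, battery$results$p_value, tolerance = 1e-12)
  report <- readLines(file.path(dir, "demo_report.md"))
  expect_true(any(grepl("density_gm_diffuse", report)))
})
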