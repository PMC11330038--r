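# Cohort-level statistical battery: nonparametric omnibus + post-hoc
# tests for CNN-derived density variables, categorical tests and ANOVA
# for demographics. All functions return tidy one-row-per-test data
# frames so results can be stacked into a report.

test_result <- function(test, statistic, df = NA_real_, p_value,
                        comparison = NA_character_, adjusted_p = NA_real_,
                        method = NA_character_, n = NA_integer_) {
  data.frame(test = test, comparison = comparison,
             statistic = as.numeric(statistic), df = as.numeric(df),
             p_value = as.numeric(p_value),
             adjusted_p = as.numeric(adjusted_p),
             method = method, n = as.integer(n),
             stringsAsFactors = FALSE)
}

as_group_list <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' Per-group summary statistics
#'
#' Continuous pipeline outputs are summarized as median with
#' interquartile range; demographics as mean with standard deviation.
#' Quartiles use linear interpolation (R's default type 7).
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @param type `"median_iqr"` or `"mean_sd"`.
#' @return Data frame with one row per group.
#' @export
summarize_groups <- function(values, groups, type = c("median_iqr", "mean_sd")) {
  type <- match.arg(type)
  groups <- factor(groups)
  out <- lapply(levels(groups), function(lv) {
    v <- values[groups == lv & !is.na(values)]
    if (!length(v))
      return(data.frame(group = lv, n = 0L, center = NA_real_,
                        spread_lo = NA_real_, spread_hi = NA_real_))
    if (type == "median_iqr") {
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(group = lv, n = length(v), center = q[2],
                 spread_lo = q[1], spread_hi = q[3])
    } else {
      data.frame(group = lv, n = length(v), center = mean(v),
                 spread_lo = mean(v) - sd(v), spread_hi = mean(v) + sd(v))
    }
  })
  out <- do.call(rbind, out)
  names(out)[3:5] <- if (type == "median_iqr")
    c("median", "q1", "q3") else c("mean", "mean_minus_sd", "mean_plus_sd")
  out
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based comparison of a numeric variable across k groups; the H
#' statistic carries the usual tie correction and is referred to a
#' chi-square distribution with k - 1 degrees of freedom. With all pooled
#' values identical H is 0 and p is 1.
#'
#' @param groups named list of numeric vectors (NAs dropped).
#' @return A one-row test-result data frame.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2 || any(lengths(groups) < 1))
    stop("need at least two nonempty groups")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    return(test_result("kruskal_wallis", 0, length(groups) - 1, 1,
                       method = "chi-square approximation",
                       n = length(pooled)))
  kt <- kruskal.test(groups)
  test_result("kruskal_wallis", unname(kt$statistic), unname(kt$parameter),
              kt$p.value, method = "chi-square approximation",
              n = length(pooled))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled ranks with tie correction,
#' following a significant Kruskal-Wallis omnibus. Two-sided p-values;
#' Bonferroni adjustment multiplies by the number of pairs and caps at 1.
#'
#' @param groups named list of numeric vectors.
#' @param adjustment only `"bonferroni"` is implemented.
#' @return Data frame with one row per group pair.
#' @export
dunn_posthoc <- function(groups, adjustment = "bonferroni") {
  adjustment <- match.arg(adjustment)
  groups <- as_group_list(groups)
  empty <- lengths(groups) == 0
  if (any(empty)) {
    message("dunn_posthoc: skipping empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  k <- length(groups)
  if (k < 2) stop("need at least two nonempty groups")
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  gidx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, gidx, mean)
  n <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_core <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  m <- k * (k - 1) / 2
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(var_core * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    rows[[length(rows) + 1]] <- test_result(
      "dunn", z, p_value = p, adjusted_p = min(1, p * m),
      comparison = paste(names(groups)[i], "vs", names(groups)[j]),
      method = paste0("z on pooled ranks, ", adjustment),
      n = n[i] + n[j])
  }
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum test for two groups
#'
#' Exact p by enumeration when the pooled sample has at most 12
#' observations and no ties; otherwise the normal approximation with tie
#' correction (no continuity correction). The method used is recorded in
#' the result.
#'
#' @param a,b numeric vectors (NAs dropped).
#' @param comparison label recorded in the result.
#' @return A one-row test-result data frame.
#' @export
wilcoxon_rank_sum <- function(a, b, comparison = "a vs b") {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  p <- min(1, wt$p.value)
  test_result("wilcoxon_rank_sum", unname(wt$statistic), p_value = p,
              comparison = comparison,
              method = if (exact) "exact enumeration"
                       else "normal approximation, tie-corrected",
              n = length(a) + length(b))
}

#' Chi-square or Fisher test on a contingency table
#'
#' `method = "auto"` follows the usual rule: Fisher's exact test when any
#' expected cell count is below 5, otherwise the chi-square test without
#' continuity correction. Zero-margin rows and columns are dropped with a
#' notice. For tables larger than 2x2 where the exact network algorithm
#' fails, a seeded Monte-Carlo Fisher p is used; the method applied is
#' recorded in the result.
#'
#' @param tab matrix of nonnegative counts.
#' @param method `"auto"`, `"chisq"`, or `"fisher"`.
#' @param B Monte-Carlo replicates for the fallback path.
#' @param mc_seed seed for the Monte-Carlo fallback.
#' @return A one-row test-result data frame.
#' @export
categorical_test <- function(tab, method = c("auto", "chisq", "fisher"),
                             B = 10000L, mc_seed = 1L) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    message("categorical_test: dropping zero-margin rows/columns")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2 after dropping zero margins")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chisq"
  if (method == "chisq") {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(test_result("categorical", unname(ct$statistic),
                       unname(ct$parameter), ct$p.value,
                       method = "chi-square, no continuity correction",
                       n = sum(tab)))
  }
  ft <- tryCatch(fisher.test(tab),
                 error = function(e) NULL)
  if (is.null(ft)) {
    ft <- with_seed(mc_seed, fisher.test(tab, simulate.p.value = TRUE, B = B))
    label <- sprintf("fisher, Monte-Carlo (B=%d)", B)
  } else {
    label <- "fisher, exact"
  }
  test_result("categorical", NA_real_, p_value = ft$p.value,
              method = label, n = sum(tab))
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within referred to F(k-1, N-k). Degenerate inputs:
#' identical groups give F = 0, p = 1; zero within-group variance with
#' unequal means gives F = Inf, p = 0.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @return A one-row test-result data frame.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with >= 2 observations each")
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0)
      return(test_result("anova", 0, df1, 1, method = "F test", n = N))
    return(test_result("anova", Inf, df1, 0, method = "F test", n = N))
  }
  f <- (ssb / df1) / (ssw / df2)
  test_result("anova", f, df1, pf(f, df1, df2, lower.tail = FALSE),
              method = "F test", n = N)
}

#' Run the cohort analysis battery
#'
#' Reproduces the analysis shape used for the density tables: per outcome
#' variable, a Kruskal-Wallis omnibus across the grouping levels,
#' followed by Dunn-Bonferroni post-hoc comparisons when the omnibus p is
#' below `posthoc_alpha`; a Wilcoxon rank-sum test when the grouping has
#' exactly two levels. Cases with a missing group label or outcome are
#' excluded per analysis (no imputation); levels listed in
#' `exclude_levels` (e.g. a deferred diagnosis) are removed before
#' testing.
#'
#' @param cohort data frame, one row per case.
#' @param grouping name of the grouping column.
#' @param outcomes character vector of numeric outcome columns.
#' @param posthoc_alpha omnibus threshold that triggers post-hoc tests.
#' @param exclude_levels group labels dropped before analysis.
#' @return List with `results` (tidy stacked test rows), `summaries`
#'   (per-outcome group summaries), and `skipped` (notices).
#' @export
run_analysis_battery <- function(cohort, grouping, outcomes,
                                 posthoc_alpha = 0.05,
                                 exclude_levels = character()) {
  stopifnot(grouping %in% names(cohort), all(outcomes %in% names(cohort)))
  results <- list(); summaries <- list(); skipped <- character()
  for (outcome in outcomes) {
    keep <- !is.na(cohort[[grouping]]) & !is.na(cohort[[outcome]]) &
      !(cohort[[grouping]] %in% exclude_levels)
    g <- factor(as.character(cohort[[grouping]][keep]))
    v <- cohort[[outcome]][keep]
    nonempty <- table(g) > 0
    if (sum(nonempty) < 2) {
      skipped <- c(skipped, sprintf(
        "%s by %s: fewer than two nonempty groups", outcome, grouping))
      next
    }
    groups <- split(v, g)
    groups <- groups[lengths(groups) > 0]
    summaries[[outcome]] <- cbind(grouping = grouping, outcome = outcome,
                                  summarize_groups(v, g))
    if (length(groups) == 2) {
      row <- wilcoxon_rank_sum(groups[[1]], groups[[2]],
                               comparison = paste(names(groups)[1], "vs",
                                                  names(groups)[2]))
      row <- cbind(grouping = grouping, outcome = outcome, row)
      results[[length(results) + 1]] <- row
    } else {
      omni <- cbind(grouping = grouping, outcome = outcome,
                    kruskal_wallis(groups))
      results[[length(results) + 1]] <- omni
      if (!is.na(omni$p_value) && omni$p_value < posthoc_alpha) {
        ph <- dunn_posthoc(groups)
        results[[length(results) + 1]] <-
          cbind(grouping = grouping, outcome = outcome, ph)
      }
    }
  }
  for (s in skipped) message("run_analysis_battery: skipped ", s)
  empty <- data.frame(grouping = character(), outcome = character(),
                      test = character(), comparison = character(),
                      statistic = numeric(), df = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      method = character(), n = integer())
  list(results = if (length(results)) do.call(rbind, results) else empty,
       summaries = summaries, skipped = skipped)
}

#' Write battery results as CSV plus a Markdown report
#'
#' @param battery result of [run_analysis_battery()].
#' @param dir output directory.
#' @param name file stem.
#' @return Paths of the written files, invisibly.
#' @export
write_battery_report <- function(battery, dir, name = "analysis") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, "_results.csv"))
  write.csv(battery$results, csv, row.names = FALSE)
  md <- file.path(dir, paste0(name, "_report.md"))
  lines <- c(sprintf("# Cohort analysis report (%s)", name), "")
  for (outcome in names(battery$summaries)) {
    s <- battery$summaries[[outcome]]
    lines <- c(lines, sprintf("## %s by %s", outcome, s$grouping[1]), "",
               paste(capture_table(s[, -(1:2)]), collapse = "\n"), "")
    r <- battery$results[battery$results$outcome == outcome, , drop = FALSE]
    if (nrow(r))
      lines <- c(lines, paste(capture_table(
        r[, c("test", "comparison", "statistic", "p_value", "adjusted_p",
              "method")]), collapse = "\n"), "")
  }
  if (length(battery$skipped))
    lines <- c(lines, "## Skipped analyses", "",
               paste("-", battery$skipped))
  writeLines(lines, md)
  invisible(c(csv, md))
}

# minimal fixed-width markdown-ish table
capture_table <- function(df) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 5) else x)
  utils::capture.output(print(df, row.names = FALSE))
}
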