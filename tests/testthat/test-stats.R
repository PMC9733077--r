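# distributed statistics vs centralized oracles on concatenated data

addr3 <- c("a@x", "b@x", "c@x")

test_that("pooled frequencies match a concatenate-and-tabulate oracle", {
  classes <- c("none", "mild", "severe")
  set.seed(201)
  raw <- lapply(1:3, function(i) sample(classes, sample(5:40, 1), replace = TRUE))
  names(raw) <- addr3
  res <- run_plan(plan_frequency(classes), raw, rng = insecure_seeded_rng(1))
  expect_equal(res$cycles_executed, 1)
  oracle <- table(factor(unlist(raw), levels = classes))
  expect_equal(unname(res$statistics$counts[classes]), as.numeric(oracle))
  # toy example from counts: (1,2) + (3,4) pools to (4,6)
  pooled <- c(a = 1, b = 2) + c(a = 3, b = 4)
  expect_equal(unname(pooled), c(4, 6))
})

test_that("chi-square from pooled cells matches the reference implementation", {
  # proportional rows are exactly independent
  tab <- matrix(c(10, 20, 30, 5, 10, 15), nrow = 2, byrow = TRUE)
  res0 <- chi_square_from_counts(tab)
  expect_equal(res0$chi_square, 0)
  expect_equal(res0$df, 2)
  expect_error(chi_square_from_counts(matrix(c(0, 0, 3, 4), 2)),
               class = "securesum_stats_error")
  set.seed(202)
  for (trial in 1:20) {
    tab <- matrix(sample(1:60, 6), nrow = 2)
    ours <- chi_square_from_counts(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$chi_square, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("the chi-square plan pools cells in one cycle", {
  rows <- c("exposed", "unexposed"); cols <- c("case", "control")
  set.seed(203)
  parties <- lapply(1:3, function(i) matrix(sample(0:30, 4), nrow = 2,
                                            dimnames = list(rows, cols)))
  names(parties) <- addr3
  res <- run_plan(plan_chi_square(rows, cols), parties, rng = insecure_seeded_rng(2))
  expect_equal(res$cycles_executed, 1)
  pooled <- Reduce(`+`, parties)
  ref <- suppressWarnings(stats::chisq.test(pooled, correct = FALSE))
  expect_equal(res$statistics$chi_square, unname(ref$statistic), tolerance = 1e-9)
})

test_that("quartiles follow the discrete inverse-CDF rule on pooled counts", {
  single <- c(only = 5)
  q <- quartiles_from_freq(single)
  expect_identical(unlist(q), c(q1 = "only", median = "only", q3 = "only"))
  # classes 1..4 with one observation each: type-1 quantiles of (1,2,3,4)
  flat <- stats::setNames(c(1, 1, 1, 1), as.character(1:4))
  q <- quartiles_from_freq(flat)
  ref <- stats::quantile(1:4, c(.25, .5, .75), type = 1)
  expect_identical(as.numeric(unlist(q)), unname(ref))
  expect_error(quartiles_from_freq(c(a = 0)), class = "securesum_stats_error")
  set.seed(204)
  for (trial in 1:20) {
    classes <- as.character(1:sample(3:9, 1))
    counts <- stats::setNames(sample(0:20, length(classes), replace = TRUE), classes)
    if (sum(counts) == 0) counts[1] <- 1
    q <- quartiles_from_freq(counts)
    raw <- as.numeric(expand_freq(counts))
    ref <- stats::quantile(raw, c(.25, .5, .75), type = 1)
    expect_identical(as.numeric(unlist(q)), unname(ref))
  }
})

test_that("grouped Wilcoxon U and z match the expand-and-rank oracle", {
  # identical distributions in both groups: U = n1 n2 / 2 and z = 0
  f <- stats::setNames(c(3, 5, 2), c("1", "2", "3"))
  sym <- wilcoxon_rank_sum(f, f)
  expect_equal(sym$U, sum(f)^2 / 2)
  expect_equal(sym$z, 0)
  expect_error(wilcoxon_rank_sum(f, f * 0), class = "securesum_stats_error")
  set.seed(205)
  for (trial in 1:20) {
    classes <- as.character(1:6)
    f1 <- stats::setNames(sample(0:15, 6, replace = TRUE), classes)
    f2 <- stats::setNames(sample(0:15, 6, replace = TRUE), classes)
    if (sum(f1) == 0) f1[2] <- 1
    if (sum(f2) == 0) f2[3] <- 1
    ours <- wilcoxon_rank_sum(f1, f2)
    x <- as.numeric(expand_freq(f1)); y <- as.numeric(expand_freq(f2))
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(ours$U, unname(ref$statistic))
    z_ref <- sign(ours$U - length(x) * length(y) / 2) *
      abs(stats::qnorm(ref$p.value / 2))
    if (is.finite(z_ref)) expect_equal(ours$z, z_ref, tolerance = 1e-6)
  }
})

test_that("the Wilcoxon plan carries both groups in a single cycle", {
  classes <- as.character(1:4)
  set.seed(206)
  parties <- lapply(1:3, function(i)
    data.frame(value = sample(classes, 30, replace = TRUE),
               group = sample(c("group1", "group2"), 30, replace = TRUE)))
  names(parties) <- addr3
  res <- run_plan(plan_wilcoxon(classes), parties, rng = insecure_seeded_rng(3))
  expect_equal(res$cycles_executed, 1)
  all_df <- do.call(rbind, parties)
  x <- as.numeric(all_df$value[all_df$group == "group1"])
  y <- as.numeric(all_df$value[all_df$group == "group2"])
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(res$statistics$U, unname(ref$statistic))
})

test_that("the pooled mean divides pooled sum by pooled count", {
  # party sums 10/4 and 20/6 pool to mean 3.0 (third party holds no data)
  parties <- list("a@x" = c(1, 2, 3, 4), "b@x" = c(2, 3, 7, 4, 2, 2),
                  "c@x" = numeric(0))
  res <- run_plan(plan_mean(), parties, rng = insecure_seeded_rng(4))
  expect_equal(res$cycles_executed, 1)
  expect_equal(res$statistics$mean, 3)
  expect_equal(res$statistics$n, 10)
  # degenerate: one party holds everything
  solo <- list("a@x" = c(5.5, 6.5), "b@x" = numeric(0), "c@x" = numeric(0))
  res <- run_plan(plan_mean(), solo, rng = insecure_seeded_rng(5))
  expect_equal(res$statistics$mean, 6)
})

test_that("the two-cycle SD equals the centralized sample SD", {
  same <- list("a@x" = rep(4.25, 5), "b@x" = rep(4.25, 3), "c@x" = rep(4.25, 2))
  res <- run_plan(plan_sd(), same, rng = insecure_seeded_rng(6))
  expect_equal(res$cycles_executed, 2)
  expect_equal(res$statistics$sd, 0)
  set.seed(207)
  parties <- lapply(1:3, function(i) round(rnorm(sample(5:50, 1), 10, 3), 3))
  names(parties) <- addr3
  res <- run_plan(plan_sd(), parties, rng = insecure_seeded_rng(7))
  expect_equal(res$statistics$sd, stats::sd(unlist(parties)), tolerance = 1e-6)
})

test_that("the two-cycle ANOVA F (and two-group t) match aov/t.test", {
  groups <- c("ctrl", "trt")
  identical_means <- list(
    "a@x" = data.frame(value = c(1, 3), group = c("ctrl", "trt")),
    "b@x" = data.frame(value = c(3, 1), group = c("ctrl", "trt")),
    "c@x" = data.frame(value = c(2, 2), group = c("ctrl", "trt")))
  res <- run_plan(plan_anova(groups), identical_means, rng = insecure_seeded_rng(8))
  expect_equal(res$cycles_executed, 2)
  expect_equal(res$statistics$F, 0)
  set.seed(208)
  parties <- lapply(1:3, function(i) {
    k <- sample(6:30, 1)
    data.frame(value = round(rnorm(k, 5, 2), 3),
               group = sample(groups, k, replace = TRUE))
  })
  names(parties) <- addr3
  all_df <- do.call(rbind, parties)
  # guard against a degenerate draw with an undersized group
  if (min(table(all_df$group)) >= 2) {
    res <- run_plan(plan_anova(groups), parties, rng = insecure_seeded_rng(9))
    ref <- stats::anova(stats::aov(value ~ group, data = all_df))
    expect_equal(res$statistics$F, ref$`F value`[1], tolerance = 1e-6)
    expect_equal(res$statistics$df1, ref$Df[1])
    expect_equal(res$statistics$df2, ref$Df[2])
    tt <- stats::t.test(value ~ group, data = all_df, var.equal = TRUE)
    expect_equal(unname(res$statistics$t), unname(tt$statistic), tolerance = 1e-6)
  }
  # three groups exercise the general ANOVA path
  g3 <- c("a", "b", "c")
  parties3 <- lapply(1:3, function(i)
    data.frame(value = round(rnorm(12, c(4, 5, 6), 1), 3),
               group = rep(g3, 4)))
  names(parties3) <- addr3
  res3 <- run_plan(plan_anova(g3), parties3, rng = insecure_seeded_rng(10))
  all3 <- do.call(rbind, parties3)
  ref3 <- stats::anova(stats::aov(value ~ group, data = all3))
  expect_equal(res3$statistics$F, ref3$`F value`[1], tolerance = 1e-6)
})

test_that("the three-cycle correlation equals Pearson r on pooled pairs", {
  exact <- lapply(1:3, function(i) { x <- round(rnorm(10, 0, 2), 3); data.frame(x = x, y = x) })
  names(exact) <- addr3
  res <- run_plan(plan_correlation(), exact, rng = insecure_seeded_rng(11))
  expect_equal(res$cycles_executed, 3)
  expect_equal(res$statistics$r, 1, tolerance = 1e-9)
  set.seed(209)
  parties <- lapply(1:3, function(i) {
    x <- round(rnorm(sample(5:40, 1), 2, 1.5), 3)
    data.frame(x = x, y = round(0.6 * x + rnorm(length(x), 0, 1), 3))
  })
  names(parties) <- addr3
  res <- run_plan(plan_correlation(), parties, rng = insecure_seeded_rng(12))
  all_df <- do.call(rbind, parties)
  expect_equal(res$statistics$r, stats::cor(all_df$x, all_df$y), tolerance = 1e-6)
  flat <- lapply(addr3, function(a) data.frame(x = rep(1, 3), y = rnorm(3)))
  names(flat) <- addr3
  expect_error(run_plan(plan_correlation(), flat, rng = insecure_seeded_rng(13)),
               class = "securesum_stats_error")
})

test_that("plans execute through the full engine and disclose only global sums", {
  parties <- list("a@x" = c(1.5, 2.5), "b@x" = c(3.5), "c@x" = c(4, 5, 6))
  res <- run_plan(plan_sd(), parties, rng = insecure_seeded_rng(14))
  # per-cycle traffic is a complete two-round protocol, never a shortcut
  for (st in res$message_stats) {
    expect_equal(st$envelopes_sent, expected_message_counts(3)$total)
  }
  # the pooled intermediates are global sums only: one value per planned
  # variable per cycle, nothing per-party
  expect_equal(lengths(res$pooled), c(2, 1))
  expect_named(res$pooled[[1]], c(".sum", ".count"))
  expect_equal(res$pooled[[1]][[".sum"]], sum(unlist(parties)))
})

test_that("run_plan enforces the three-party protocol minimum", {
  expect_error(run_plan(plan_mean(), list("a@x" = 1, "b@x" = 2)),
               class = "securesum_stats_error")
})
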