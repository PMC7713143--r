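paper_t1_callus <- group_summary(c("LS", "VFLS3", "VFLS6"),
                                 c(8.9, 12.5, 17.1), c(1.6, 3.5, 5.1),
                                 rep(6, 3))

test_that("identical groups give F = 0, p = 1 and all Tukey p = 1", {
  g <- group_summary(c("a", "b", "c"), c(5, 5, 5), c(1, 1, 1), c(6, 6, 6))
  a <- anova_from_summary(g)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_equal(tukey_from_summary(g)$p_adj, rep(1, 3))
})

test_that("published whole-bone callus volume summaries reproduce the ANOVA", {
  a <- anova_from_summary(paper_t1_callus)
  expect_equal(unname(a$df), c(2, 15))
  expect_equal(a$p, 0.0056, tolerance = 0.0005 / 0.0056)
  tk <- tukey_from_summary(paper_t1_callus)
  expect_equal(tk$p_adj[tk$pair == "VFLS6/LS"], 0.0042,
               tolerance = 0.0005 / 0.0042)
})

test_that("summary ANOVA equals raw-data ANOVA on moment-matched data", {
  set.seed(4)
  mk <- function(m, s, n) { z <- rnorm(n); m + s * (z - mean(z)) / sd(z) }
  for (rep in 1:5) {
    m <- runif(3, 5, 20); s <- runif(3, 0.5, 4); n <- c(6, 6, 6)
    vals <- c(mk(m[1], s[1], 6), mk(m[2], s[2], 6), mk(m[3], s[3], 6))
    gr <- factor(rep(c("a", "b", "c"), each = 6))
    raw <- anova(aov(vals ~ gr))
    sum_res <- anova_from_summary(group_summary(c("a", "b", "c"), m, s, n))
    expect_equal(sum_res$F, raw$`F value`[1], tolerance = 1e-10)
    expect_equal(sum_res$p, raw$`Pr(>F)`[1], tolerance = 1e-10)
    tk_raw <- TukeyHSD(aov(vals ~ gr))$gr[, "p adj"]
    tk_sum <- tukey_from_summary(group_summary(c("a", "b", "c"), m, s, n))
    expect_equal(tk_sum$p_adj,
                 unname(tk_raw[c("b-a", "c-a", "c-b")]), tolerance = 1e-8)
  }
})

test_that("Tukey matches a hand-computed studentized range on a toy design", {
  # 3 groups, n = 4: means 10/12/16, pooled within-SD 2
  g <- group_summary(c("a", "b", "c"), c(10, 12, 16), c(2, 2, 2), c(4, 4, 4))
  tk <- tukey_from_summary(g)
  q_hand <- (16 - 10) / sqrt(4 / 4)     # |diff| / sqrt(MSW / n) = 6
  expect_equal(tk$q[tk$pair == "c/a"], q_hand)
  expect_equal(tk$p_adj[tk$pair == "c/a"],
               ptukey(q_hand, 3, 9, lower.tail = FALSE))
})

test_that("p decreases monotonically as group separation grows", {
  ps <- sapply(seq(0, 4, by = 0.5), function(delta) {
    anova_from_summary(group_summary(c("a", "b", "c"),
                                     c(10, 10 + delta, 10 + 2 * delta),
                                     c(2, 2, 2), c(6, 6, 6)))$p
  })
  expect_true(all(diff(ps) < 1e-12))
})

test_that("zero within-variance with unequal means is flagged with p = 0", {
  g <- group_summary(c("a", "b"), c(1, 2), c(0, 0), c(3, 3))
  a <- anova_from_summary(g)
  expect_equal(a$p, 0)
  expect_equal(a$flag, "zero_within_variance")
})

test_that("percent differences reproduce the printed-table convention", {
  expect_equal(percent_difference(12.5, 8.9), 40)     # integer rounding
  expect_equal(percent_difference(7, 7), 0)
  expect_equal(percent_difference(9.3, 6.0), 55)
  expect_equal(percent_difference(c(4.4, 5.4) , 4.9, digits = 1),
               c(-10.2, 10.2))
  expect_equal(percent_difference(5.4, 4.4, digits = 1), 22.7)
  expect_error(percent_difference(1, 0), "non-zero")
  # half away from zero, not banker's rounding
  expect_equal(percent_difference(10.25, 10, digits = 1), 2.5)
  expect_equal(percent_difference(9.75, 10, digits = 1), -2.5)
})

test_that("comparison tables assemble summaries, tests and percent columns", {
  set.seed(11)
  d <- draw_group_volumes(8.9, c(LS = 1, VFLS3 = 1.4, VFLS6 = 1.93),
                          n_per_group = 6, cv = 0.25, seed = 3)
  long <- data.frame(sample = d$sample, group = d$group,
                     variable = "callus_volume", value = d$volume)
  tab <- build_comparison_table(long, group_order = c("LS", "VFLS3", "VFLS6"))
  expect_equal(nrow(tab$summary), 3L)
  expect_equal(tab$summary$label, c("LS", "VFLS3", "VFLS6"))
  expect_equal(nrow(tab$posthoc), 3L)
  expect_equal(tab$percent_diffs$pair,
               c("VFLS3/LS", "VFLS6/LS", "VFLS6/VFLS3"))
  # summary-table input path gives identical results
  tab2 <- build_comparison_table(
    data.frame(variable = "callus_volume", label = tab$summary$label,
               mean = tab$summary$mean, sd = tab$summary$sd,
               n = tab$summary$n),
    group_order = c("LS", "VFLS3", "VFLS6"))
  expect_equal(tab2$anova$p, tab$anova$p)
  # missing values are flagged, not silently dropped
  long$value[1] <- NA
  expect_warning(build_comparison_table(long), "flagged")
})

test_that("zero-variance input exercises the flagged ANOVA path", {
  long <- data.frame(sample = 1:6, group = rep(c("a", "b"), each = 3),
                     variable = "v", value = rep(c(1, 2), each = 3))
  tab <- build_comparison_table(long)
  expect_equal(tab$anova$flag, "zero_within_variance")
  expect_equal(tab$anova$p, 0)
})

test_that("paired signed-rank comparison of cis vs trans volumes", {
  # rigid-fixation-like pattern: cis consistently below trans
  cis <- c(2.1, 2.3, 2.2, 2.5, 2.0, 2.4)
  trans <- c(3.5, 3.9, 3.7, 4.2, 3.3, 3.6)
  ht <- compare_cis_trans(cis, trans)
  expect_lt(ht$p.value, 0.05)
  # symmetric pattern: no significant difference
  ht2 <- compare_cis_trans(trans + c(0.11, -0.09, 0.18, -0.21, 0.13, -0.12),
                           trans)
  expect_gt(ht2$p.value, 0.3)
  expect_error(compare_cis_trans(1:3, 1:4), "paired")
})
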