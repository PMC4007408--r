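test_that("survival percentages count new expressers and scale-invariantly", {
  tab <- data.frame(condition = "c",
                    present_at_t1 = rep(c(TRUE, FALSE), c(10, 0)),
                    present_at_t2 = rep(c(TRUE, FALSE), c(8, 2)),
                    newly_appeared = FALSE)
  expect_equal(survival_percent(tab, "c")$pct_survival, 80)
  tab2 <- rbind(tab, data.frame(condition = "c", present_at_t1 = FALSE,
                                present_at_t2 = TRUE, newly_appeared = TRUE))
  tab2$present_at_t2[9:10] <- TRUE
  expect_equal(survival_percent(tab2, "c")$pct_survival, 110)
  doubled <- rbind(tab, tab)
  expect_equal(survival_percent(doubled, "c")$pct_survival, 80)
})

test_that("the pooled t-test matches its closed form and conventions", {
  a <- c(1, 2, 3); b <- a + 10
  r <- ttest_unpaired(a, b)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_manual)
  expect_lt(r$p_value, 0.01)
  same <- ttest_unpaired(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ident <- ttest_unpaired(a, a)
  expect_equal(ident$statistic, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1)
})

test_that("one-way ANOVA matches a hand-computed decomposition and F = t^2", {
  g <- list(c(1, 3, 2, 4), c(5, 6, 4, 7), c(2, 2, 3, 1))
  r <- anova_oneway(g)
  y <- unlist(g)
  ssb <- sum(vapply(g, function(x) 4 * (mean(x) - mean(y))^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  expect_equal(r$statistic, (ssb / 2) / (ssw / 9))
  expect_equal(r$df, c(2, 9))
  ident <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  with_seed(5, {
    a <- rnorm(12); b <- rnorm(15, 0.8)
    expect_equal(anova_oneway(list(a, b))$statistic,
                 ttest_unpaired(a, b)$statistic^2, tolerance = 1e-9)
  })
})

test_that("Newman-Keuls agrees with the t-test for two groups and isolates an outlying mean", {
  with_seed(8, {
    for (i in 1:20) {
      a <- rnorm(8); b <- rnorm(8, runif(1, 0, 1.5))
      nk <- newman_keuls(list(a, b))
      tt <- ttest_unpaired(a, b)
      expect_equal(nk$pairwise$significant[1], tt$p_value < 0.05)
    }
    g <- list(rnorm(10), rnorm(10), rnorm(10, 10))
    nk3 <- newman_keuls(g, group_names = c("A", "B", "C"))
    pw <- nk3$pairwise
    expect_true(all(pw$significant[pw$group1 == "C" | pw$group2 == "C"]))
    expect_false(any(pw$significant[pw$group1 != "C" & pw$group2 != "C"]))
  })
})

test_that("Newman-Keuls significance is monotone in mean separation", {
  with_seed(9, {
    base <- list(rnorm(10, 0, 1), rnorm(10, 0, 1))
    qs <- vapply(c(0.5, 1, 2, 4), function(d) {
      g <- base; g[[2]] <- g[[2]] - mean(g[[2]]) + d
      newman_keuls(g)$pairwise$q[1]
    }, 0)
    expect_true(all(diff(qs) > 0))
    ident <- newman_keuls(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
    expect_false(any(ident$pairwise$significant))
  })
})
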