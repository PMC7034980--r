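make_table <- function(groups) {
  do.call(rbind, lapply(names(groups), function(g)
    data.frame(junction_class = g, m1_coverage_index = groups[[g]])))
}

test_that("two identical samples are not distinguished by Mann-Whitney", {
  set.seed(4)
  x <- rnorm(40, 50, 5)
  tab <- make_table(list(control = x, treated = x))
  cmp <- compare_groups(tab, "m1_coverage_index")
  expect_equal(cmp$method, "Mann-Whitney U")
  expect_gt(cmp$p_value, 0.95)
})

test_that("a 3-SD shift at n = 100 is detected, consistent with a permutation test", {
  set.seed(8)
  x <- rnorm(100, 50, 5)
  y <- rnorm(100, 65, 5)
  tab <- make_table(list(control = x, treated = y))
  cmp <- compare_groups(tab, "m1_coverage_index")
  expect_lt(cmp$p_value, 1e-3)
  expect_lt(perm_test(x, y), 1e-3)

  # a subtle shift: Mann-Whitney and permutation agree on the verdict
  set.seed(9)
  a <- rnorm(60, 50, 5)
  b <- rnorm(60, 51, 5)
  tab2 <- make_table(list(control = a, treated = b))
  p_mw <- compare_groups(tab2, "m1_coverage_index")$p_value
  p_perm <- perm_test(a, b, 4000L)
  expect_equal(p_mw < 0.05, p_perm < 0.05)
})

test_that("three identical groups give uniformly non-significant Games-Howell", {
  set.seed(12)
  x <- rnorm(50, 30, 6)
  tab <- make_table(list(a = x, b = x, c = x))
  cmp <- compare_groups(tab, "m1_coverage_index")
  expect_equal(cmp$method, "one-way ANOVA + Games-Howell")
  expect_true(all(cmp$pairwise$p > 0.9))
  expect_true(all(c("shapiro_p", "ks_lilliefors_p") %in%
                    names(cmp$normality)))
})

test_that("Games-Howell flags only the shifted group under unequal variances", {
  set.seed(13)
  a <- rnorm(80, 50, 2)
  b <- rnorm(40, 50, 8)      # same centre, wider spread, smaller n
  c <- rnorm(60, 58, 4)      # shifted
  gh <- games_howell(c(a, b, c), rep(c("a", "b", "c"), c(80, 40, 60)))
  pab <- gh$p[gh$group1 == "a" & gh$group2 == "b"]
  expect_gt(pab, 0.05)
  expect_lt(gh$p[gh$group1 == "a" & gh$group2 == "c"], 0.01)
  expect_lt(gh$p[gh$group1 == "b" & gh$group2 == "c"], 0.01)
  # cross-check the null pair against a permutation oracle
  expect_gt(perm_test(a, b, 4000L), 0.05)
  expect_error(games_howell(c(a, b), rep(c("a", "b"), c(80, 40))),
               ">= 3 groups")
})

test_that("group comparison validates its inputs", {
  tab <- make_table(list(control = rnorm(10), treated = rnorm(2)))
  expect_error(compare_groups(tab, "m1_coverage_index"), "too small")
  expect_error(compare_groups(tab, "nope"), "unknown parameter")
  only <- make_table(list(control = rnorm(10)))
  expect_error(compare_groups(only, "m1_coverage_index"), ">= 2 groups")
})

test_that("control-normalized profiles scale medians to 100", {
  set.seed(30)
  x <- rnorm(60, 40, 4)
  same <- make_table(list(control = x, treated = x))
  fp <- normalize_profile(same, "control",
                          parameters = "m1_coverage_index")
  expect_equal(fp$normalized, 100)
  expect_false(fp$significant)

  half <- make_table(list(control = rep(c(40, 42, 44), 20),
                          treated = rep(c(20, 21, 22), 20)))
  fp2 <- normalize_profile(half, "control",
                           parameters = "m1_coverage_index")
  expect_equal(fp2$normalized, 50)
  expect_true(fp2$significant)

  zero <- make_table(list(control = rep(0, 10), treated = rnorm(10, 5)))
  fp3 <- normalize_profile(zero, "control",
                           parameters = "m1_coverage_index")
  expect_true(is.na(fp3$normalized))
  expect_match(fp3$note, "non-normalizable")
  expect_error(normalize_profile(half, "absent"), "absent")
})
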