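test_that("a known difference-of-differences pattern gives interaction F = 3", {
  tab <- NULL
  dd <- c(2, 0, 2, 0)
  for (s in 1:4)
    tab <- rbind(tab, data.frame(
      subject = s, intervention = c("active", "active", "sham", "sham"),
      block = c("pre", "post", "pre", "post"),
      value = c(0, dd[s], 0, 0)))
  res <- rm_anova_2x2(condition_table(tab$subject, tab$intervention,
                                      tab$block, tab$value))
  int <- res[res$effect == "Interaction", ]
  expect_equal(int$F, 3)
  expect_equal(c(int$df1, int$df2), c(1, 3))
})

test_that("pure between-subject variation yields zero F for all effects", {
  tab <- expand.grid(subject = 1:5, intervention = c("active", "sham"),
                     block = c("pre", "post"), stringsAsFactors = FALSE)
  tab$value <- as.numeric(tab$subject) * 2   # constant within subject
  res <- rm_anova_2x2(condition_table(tab$subject, tab$intervention,
                                      tab$block, tab$value))
  expect_equal(res$F, c(0, 0, 0))
})

test_that("ANOVA agrees with brute-force sums of squares on random tables", {
  for (r in 1:20) {
    tab <- simulate_condition_table(n_subjects = 3 + (r %% 6),
                                    block_shift = 0.2,
                                    interaction_shift = 0.1,
                                    rng_seed = 1000 + r)
    mine <- rm_anova_2x2(tab)
    oracle <- brute_force_anova(tab)
    expect_equal(mine$F, oracle$F, tolerance = 1e-10)
    expect_equal(mine$partial_eta_sq, oracle$partial_eta_sq,
                 tolerance = 1e-10)
  }
})

test_that("ANOVA agrees with the aov error-strata decomposition", {
  tab <- simulate_condition_table(n_subjects = 9, block_shift = 0.4,
                                  interaction_shift = 0.15, rng_seed = 77)
  mine <- rm_anova_2x2(tab)
  a <- summary(stats::aov(value ~ block * intervention +
                            Error(subject / (block * intervention)),
                          data = tab))
  expect_equal(mine$F[1],
               a[["Error: subject:block"]][[1]]["block", "F value"],
               tolerance = 1e-10)
  expect_equal(mine$F[2],
               a[["Error: subject:intervention"]][[1]][
                 "intervention", "F value"], tolerance = 1e-10)
  expect_equal(mine$F[3],
               a[["Error: subject:block:intervention"]][[1]][
                 "block:intervention", "F value"], tolerance = 1e-10)
})

test_that("interaction F equals the squared paired t on difference-of-differences", {
  for (r in 1:10) {
    tab <- simulate_condition_table(n_subjects = 4 + r, block_shift = 0.3,
                                    interaction_shift = 0.2,
                                    rng_seed = 50 + r)
    m <- rm_anova_2x2(tab)
    cell <- function(iv, bl) tab$value[tab$intervention == iv &
                                         tab$block == bl][
      order(tab$subject[tab$intervention == iv & tab$block == bl])]
    dd <- (cell("active", "post") - cell("active", "pre")) -
      (cell("sham", "post") - cell("sham", "pre"))
    t_stat <- mean(dd) / (stats::sd(dd) / sqrt(length(dd)))
    expect_equal(m$F[m$effect == "Interaction"], t_stat^2,
                 tolerance = 1e-9)
  }
})

test_that("partial eta squared satisfies the F-df identity", {
  for (r in 1:10) {
    tab <- simulate_condition_table(n_subjects = 5 + r,
                                    block_shift = 0.2,
                                    interaction_shift = 0.1,
                                    rng_seed = 300 + r)
    res <- rm_anova_2x2(tab)
    expect_equal(res$partial_eta_sq,
                 res$F * res$df1 / (res$F * res$df1 + res$df2),
                 tolerance = 1e-10)
  }
})

test_that("incomplete tables are refused with a named cell", {
  tab <- simulate_condition_table(n_subjects = 4, rng_seed = 2)
  broken <- tab[-3, ]
  expect_error(condition_table(broken$subject, broken$intervention,
                               broken$block, broken$value),
               "incomplete")
})

test_that("post-hoc family is exactly the four printed contrasts", {
  tab <- simulate_condition_table(n_subjects = 8, block_shift = 0.5,
                                  interaction_shift = 0.3, rng_seed = 4)
  ph <- posthoc_paired_tests(tab)
  expect_equal(nrow(ph), 4)
  expect_setequal(ph$contrast,
                  c("sham pre vs sham post", "active pre vs active post",
                    "sham pre vs active pre", "sham post vs active post"))
  expect_true(all(ph$df == 7))
})

test_that("paired t matches the hand formula and degenerate cases", {
  tab <- NULL
  diffs <- c(1, 1, 1, 2)
  for (s in 1:4)
    tab <- rbind(tab, data.frame(
      subject = s, intervention = c("sham", "sham", "active", "active"),
      block = c("pre", "post", "pre", "post"),
      value = c(diffs[s], 0, 0, 0)))
  ph <- posthoc_paired_tests(condition_table(tab$subject,
                                             tab$intervention, tab$block,
                                             tab$value))
  t_hand <- mean(diffs) / (stats::sd(diffs) / sqrt(4))
  row <- ph[ph$contrast == "sham pre vs sham post", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)

  same <- simulate_condition_table(n_subjects = 5, rng_seed = 6)
  same$value <- 1
  ph0 <- posthoc_paired_tests(condition_table(same$subject,
                                              same$intervention,
                                              same$block, same$value))
  expect_true(all(ph0$t == 0))
  expect_true(all(ph0$p == 1))
})

test_that("Bonferroni thresholds divide the family alpha", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.03, 1), 0.03)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
})

test_that("interaction power reduces to alpha under the null and obeys lambda", {
  expect_equal(interaction_power(power_spec(0, 15)), 0.05,
               tolerance = 1e-12)
  # eta = 0.5 -> f2 = 1; N = 8, m = 2, rho = 0.5 -> lambda = 32
  s <- power_spec(0.5, 8)
  f2 <- 0.5 / 0.5
  lambda <- f2 * 8 * 2 / (1 - 0.5)
  expect_equal(lambda, 32)
  df2 <- (8 - 2) * 1
  expect_equal(interaction_power(s),
               stats::pf(stats::qf(0.95, 1, df2), 1, df2, ncp = 32,
                         lower.tail = FALSE))
})

test_that("power is strictly increasing in N, effect size and correlation", {
  p_n <- sapply(c(8, 12, 16, 24), function(n)
    interaction_power(power_spec(0.2, n)))
  expect_true(all(diff(p_n) > 0))
  p_eta <- sapply(c(0.05, 0.1, 0.2, 0.4), function(e)
    interaction_power(power_spec(e, 12)))
  expect_true(all(diff(p_eta) > 0))
  p_rho <- sapply(c(0.2, 0.5, 0.7), function(r)
    interaction_power(power_spec(0.2, 12, rho = r)))
  expect_true(all(diff(p_rho) > 0))
})

test_that("required sample size is minimal and monotone in effect size", {
  for (e in c(0.1, 0.14, 0.23)) {
    spec <- power_spec(e, N = 10)
    n <- required_sample_size(spec, 0.8)
    s_n <- spec; s_n$N <- n
    expect_gte(interaction_power(s_n), 0.8)
    if (n > spec$g + 1) {
      s_m <- spec; s_m$N <- n - 1
      expect_lt(interaction_power(s_m), 0.8)
    }
  }
  ns <- sapply(c(0.08, 0.14, 0.23, 0.4), function(e)
    required_sample_size(power_spec(e, N = 10), 0.8))
  expect_true(all(diff(ns) <= 0))
})
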