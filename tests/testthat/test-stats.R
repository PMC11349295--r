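test_that("reference design yields the expected df structure", {
  # 2 conditions x 9 EKMr levels, 3 and 4 replicates: 63 observations,
  # interaction df (2-1)(9-1) = 8, error df 63 - 18 = 45
  obs <- rbind(make_obs("n", 1:9, 3, sd = 1, seed = 1),
               make_obs("g", 1:9, 4, sd = 1, seed = 2))
  a <- two_way_anova(obs)
  it <- interaction_test(a)
  expect_identical(it$df1, 8L)
  expect_identical(it$df2, 45L)
  expect_identical(a$effects$df[a$effects$term == "ekmr_level"], 8L)
  expect_identical(a$effects$df[a$effects$term == "condition"], 1L)
})

test_that("balanced designs match the brute-force cell-means decomposition", {
  # 2 x 2 with hand-computable cell means
  m22 <- matrix(c(1, 3, 2, 8), 2)  # rows conditions, cols levels
  obs <- make_obs(c("a", "b"), 1:2, 3, means = m22, sd = 0.5, seed = 4)
  a <- two_way_anova(obs)
  bf <- bf_anova_balanced(obs)
  eff <- a$effects
  expect_equal(eff$sum_sq[eff$term == "condition"], unname(bf$ss["condition"]))
  expect_equal(eff$sum_sq[eff$term == "ekmr_level"], unname(bf$ss["ekmr_level"]))
  expect_equal(eff$sum_sq[eff$term == "condition:ekmr_level"],
               unname(bf$ss["interaction"]))
  expect_equal(eff$sum_sq[eff$term == "Residuals"], unname(bf$ss["error"]))
  expect_equal(interaction_test(a)$F, unname(bf$F_int))
  # SS decomposition identity on the balanced design
  expect_equal(sum(eff$sum_sq), unname(bf$ss["total"]))

  # 3 x 3 x 3 random means
  m33 <- matrix(withr::with_seed(8, stats::rnorm(9, 5, 2)), 3)
  obs3 <- make_obs(c("a", "b", "c"), 1:3, 3, means = m33, sd = 1, seed = 9)
  a3 <- two_way_anova(obs3)
  bf3 <- bf_anova_balanced(obs3)
  expect_equal(a3$effects$sum_sq[a3$effects$term == "condition:ekmr_level"],
               unname(bf3$ss["interaction"]))
  expect_equal(interaction_test(a3)$F, unname(bf3$F_int))
})

test_that("unbalanced interaction F equals the model-comparison F", {
  obs <- rbind(make_obs("n", 1:9, 3, sd = 1, seed = 5),
               make_obs("g", 1:9, 4, sd = 1, seed = 6))
  obs$intensity <- obs$intensity + as.numeric(obs$ekmr_level) * 0.3
  a <- two_way_anova(obs)
  d <- data.frame(condition = factor(obs$condition),
                  ekmr_level = factor(obs$ekmr_level),
                  intensity = obs$intensity)
  full <- stats::lm(intensity ~ condition * ekmr_level, data = d)
  add <- stats::lm(intensity ~ condition + ekmr_level, data = d)
  cmp <- stats::anova(add, full)
  expect_equal(interaction_test(a)$F, cmp$F[2], tolerance = 1e-10)
  expect_equal(interaction_test(a)$p, cmp$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("degenerate and inestimable inputs are handled explicitly", {
  # identical value in every cell: zero error SS, no crash
  obs <- make_obs(c("a", "b"), 1:3, 2, sd = 0)
  obs$intensity <- 1
  a <- two_way_anova(obs)
  expect_equal(a$effects$sum_sq[a$effects$term == "Residuals"], 0)
  # empty cell
  obs2 <- rbind(make_obs("a", 1:3, 2, sd = 1, seed = 1),
                make_obs("b", 1:2, 2, sd = 1, seed = 2))
  expect_error(two_way_anova(obs2), "empty")
  expect_error(two_way_anova(make_obs("a", 1:3, 2, sd = 1)), "2 conditions")
})

test_that("Bonferroni post hoc multiplies by the level count and caps at 1", {
  obs <- rbind(make_obs("n", 1:9, 3, sd = 1, seed = 10),
               make_obs("g", 1:9, 4, sd = 1, seed = 11))
  obs$intensity[obs$condition == "g" & obs$ekmr_level == 4] <- 10
  a <- two_way_anova(obs)
  ph <- bonferroni_posthoc(a)
  expect_identical(nrow(ph), 9L)
  expect_equal(ph$bonferroni_p, pmin(ph$raw_p * 9, 1))
  # cross-check against p.adjust
  expect_equal(ph$bonferroni_p, stats::p.adjust(ph$raw_p, "bonferroni"))
  expect_true(all(ph$bonferroni_p >= ph$raw_p))
  expect_true(ph$significant[ph$ekmr_level == 4])
  # a level with identical condition means has raw p = 1
  obs$intensity[obs$ekmr_level == 7] <- 2
  ph2 <- bonferroni_posthoc(two_way_anova(obs))
  expect_equal(ph2$raw_p[ph2$ekmr_level == 7], 1)
})
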