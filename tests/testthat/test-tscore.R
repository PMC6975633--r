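# T-score propagation, WHO/NASA classification, and reproduction of the
# published assessment grid from back-solved reference BMDs.

test_that("post-mission BMD and T-score arithmetic", {
  expect_identical(post_mission_bmd(0.9, 0), 0.9)
  expect_identical(post_mission_bmd(0.9, 100), 0)
  expect_equal(post_mission_bmd(0.8863, 15.52), 0.74876, tolerance = 1e-4)
  expect_identical(t_score(0.858), 0)
  expect_equal(t_score(0.738), -1)
  expect_equal(t_score(0.594), -2.2)
  expect_error(post_mission_bmd(0.9, 101), "0, 100")
  expect_error(t_score(-0.1), "non-negative")
})

test_that("back-solving a pre-mission BMD round-trips exactly", {
  expect_identical(backsolve_premission_bmd(0, 0), 0.858)
  expect_equal(backsolve_premission_bmd(-0.91, 15.52), 0.88638,
               tolerance = 1e-4)
  set.seed(2)
  for (i in 1:25) {
    ts <- runif(1, -3, 1); loss <- runif(1, 0, 60)
    pre <- backsolve_premission_bmd(ts, loss)
    expect_equal(t_score(post_mission_bmd(pre, loss)), ts, tolerance = 1e-12)
  }
  expect_error(backsolve_premission_bmd(0, 100), "below 100")
  expect_error(backsolve_premission_bmd(-8, 0), "non-positive")
})

test_that("WHO classes partition the line with the stated boundaries", {
  expect_identical(as.character(classify_who(c(-0.5, 0, 2))),
                   rep("normal", 3))
  expect_identical(as.character(classify_who(-1.5)), "osteopenia")
  expect_identical(as.character(classify_who(c(-2.5, -3))),
                   rep("osteoporosis", 2))
  # boundary conventions: T = -1 normal (exclusive), T = -2.5 osteoporotic
  expect_identical(as.character(classify_who(-1)), "normal")
  expect_identical(as.character(classify_who(-2.5)), "osteoporosis")
  ts <- seq(-4, 1, by = 0.01)
  expect_false(anyNA(classify_who(ts)))
  expect_error(classify_who(NaN), "finite")
})

test_that("NASA permissible limit is strict at -2", {
  expect_true(nasa_permissible(-1.99))
  expect_false(nasa_permissible(-2.01))
  expect_false(nasa_permissible(-2))
  expect_true(nasa_permissible(0))
})

test_that("assessment grid reproduces the published T-scores", {
  groups <- read_reference_groups(
    marsbmd_extdata("reference_groups_synthetic.csv"))
  a <- assess_mission(paper_model(), groups, c(400, 600, 1000, 1200))
  expect_identical(nrow(a), 48L)
  printed <- table3_grid()
  mrg <- merge(a, printed,
               by = c("sex", "ethnicity", "age_min", "age_max"),
               suffixes = c("", "_printed"))
  mrg <- mrg[mrg$mission_days == mrg$duration_days, ]
  expect_identical(nrow(mrg), 48L)
  err <- abs(mrg$t_score - mrg$t_score_printed)
  expect_gte(sum(err <= 0.05), 44)   # a few cells carry paper-internal drift
  expect_lte(max(err), 0.08)
  # spot anchor: white male 30-39 at 600 days
  spot <- mrg[mrg$sex == "male" & mrg$ethnicity == "non-Hispanic white" &
                mrg$age_min == 30 & mrg$mission_days == 600, ]
  expect_equal(spot$t_score, -1.38, tolerance = 0.01)
  # post-BMD identity holds to machine precision
  expect_equal(a$post_bmd,
               a$premission_bmd_g_cm2 * (100 - a$predicted_loss_pct) / 100,
               tolerance = 1e-12)
  expect_error(assess_mission(paper_model(), groups, c(400, 400)),
               "duplicate")
})

test_that("risk is monotone in mission duration for every group", {
  groups <- read_reference_groups(
    marsbmd_extdata("reference_groups_synthetic.csv"))
  a <- assess_mission(paper_model(), groups, seq(0, 1200, by = 200))
  sev <- c(normal = 0, osteopenia = 1, osteoporosis = 2)
  for (k in split(a, interaction(a$sex, a$ethnicity, a$age_min, drop = TRUE))) {
    k <- k[order(k$mission_days), ]
    expect_true(all(diff(k$t_score) < 0))
    expect_true(all(diff(sev[as.character(k$who_class)]) >= 0))
  }
  # at duration 0 a reference-mean group scores exactly 0
  g0 <- data.frame(sex = "female", ethnicity = "non-Hispanic white",
                   age_min = 20, age_max = 29, premission_bmd_g_cm2 = 0.858)
  expect_equal(assess_mission(paper_model(), g0, 0)$t_score, 0)
})

test_that("scenario summaries count the printed conjunction grid correctly", {
  printed <- table3_grid()
  printed$mission_days <- printed$duration_days
  s <- summarize_classifications(printed, mission_scenario("conjunction"))
  expect_identical(s$n_cells, 24L)
  expect_identical(s$n_non_permissible, 19L)
  expect_identical(s$n_osteoporosis, 8L)
  expect_identical(s$n_osteopenia_or_worse, 24L)
  # degenerate inputs
  one <- data.frame(mission_days = 1000, t_score = -3)
  s1 <- summarize_classifications(one, mission_scenario("conjunction"))
  expect_equal(c(s1$pct_non_permissible, s1$pct_osteoporosis,
                 s1$pct_osteopenia_or_worse), c(100, 100, 100))
  zero <- data.frame(mission_days = c(400, 600), t_score = c(0, 0))
  s0 <- summarize_classifications(zero, mission_scenario("opposition"))
  expect_equal(c(s0$pct_non_permissible, s0$pct_osteoporosis,
                 s0$pct_osteopenia_or_worse), c(0, 0, 0))
  expect_error(summarize_classifications(one, mission_scenario("opposition")),
               "no assessments")
})

test_that("unpaired t-test matches hand arithmetic and is antisymmetric", {
  r <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_identical(r$df, 4)
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sw <- two_sample_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$statistic, -r$statistic)
  expect_equal(sw$p_value, r$p_value)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least two")
  expect_error(two_sample_ttest(c(2, 2), c(2, 2)), "zero variance")
})
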