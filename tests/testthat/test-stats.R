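cm_from_edge <- function(values_by_subject, i = 1, j = 2, base_seed = 500) {
  # list of matrices identical except edge (i, j) carries the given values
  lapply(seq_along(values_by_subject), function(s) {
    m <- unclass(random_cm(base_seed))
    m[i, j] <- m[j, i] <- values_by_subject[s]
    cstcnet:::new_connectivity_matrix(m, "static_z")
  })
}

test_that("pooled two-sample t matches the hand computation", {
  a <- cm_from_edge(c(1, 2, 3))
  b <- cm_from_edge(c(2, 3, 4))
  res <- edgewise_ttest(a, b)
  row <- res[res$i == 1 & res$j == 2, ]
  expect_equal(row$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(row$p, 2 * pt(-1.2247449, df = 4), tolerance = 1e-6)
  # all other edges identical across subjects -> zero variance -> NA
  expect_true(all(is.na(res$p[!(res$i == 1 & res$j == 2)])))
  expect_false(any(res$significant[!(res$i == 1 & res$j == 2)]))
})

test_that("identical groups give t = 0 and no significant edge", {
  mats <- lapply(1:4, function(s) random_cm(s))
  res <- edgewise_ttest(mats, mats)
  expect_true(all(res$statistic[!is.na(res$statistic)] == 0))
  expect_false(any(res$significant))
  expect_error(edgewise_ttest(mats[1], mats), "2 subjects")
  expect_error(
    edgewise_ttest(mats, lapply(1:4, function(s) random_cm(s, "dfc_sd_z"))),
    "kinds")
})

test_that("edgewise results are invariant to matrix transposition", {
  g1 <- lapply(1:5, random_cm)
  g2 <- lapply(6:10, random_cm)
  tr <- function(lst) lapply(lst, function(m)
    cstcnet:::new_connectivity_matrix(t(unclass(m)), "static_z"))
  r1 <- edgewise_ttest(g1, g2)
  r2 <- edgewise_ttest(tr(g1), tr(g2))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand step-up on the printed example", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  q <- bh_fdr(p)
  # step-up: q_(k) = min over j >= k of p_(j) * m / j
  expect_equal(q, c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(sum(q < 0.05), 3)
  expect_equal(bh_fdr(rep(1, 6)), rep(1, 6))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the empirical FDR on null edge cohorts", {
  set.seed(66)
  n_rep <- 60
  rejections <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    p <- runif(190)
    rejections[r] <- sum(bh_fdr(p) < 0.05)
  }
  # under the global null, any rejection is a false discovery
  fdp <- mean(rejections > 0)
  expect_lte(fdp, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("duration correlation is exact on linear data and errors sanely", {
  dur <- c(2, 5, 9, 14, 20)
  mats <- cm_from_edge(0.5 - 0.02 * dur)
  res <- edgewise_duration_correlation(mats, dur)
  row <- res[res$i == 1 & res$j == 2, ]
  expect_equal(row$statistic, -1, tolerance = 1e-10)
  expect_lt(row$p, 1e-8)
  expect_error(edgewise_duration_correlation(mats, rep(3, 5)), "constant")
  expect_error(edgewise_duration_correlation(mats[1:3], dur[1:3]), "4 subjects")
})

test_that("planted negative duration slope is recovered and significant", {
  slopes <- data.frame(roi_i = "thalamus_somatosensory",
                       roi_j = "cortex_somatosensory",
                       group = "GE", slope = -0.02)
  sim <- simulate_edge_cohort(c(GE = 60), duration_slopes = slopes,
                              noise_sd = 0.1, seed = 12)
  res <- edgewise_duration_correlation(sim$matrices, sim$duration_years)
  target <- res$edge == "cortex_somatosensory..thalamus_somatosensory"
  expect_lt(res$statistic[target], 0)
  expect_true(res$significant[target])
  # null edges reject at about the nominal rate before FDR
  expect_lt(mean(res$p[!target] < 0.05), 0.05 + 2 * sqrt(0.05 / 189))
})

test_that("interaction coefficient is exact on noiseless constructions", {
  dur <- c(1, 3, 5, 8, 2, 4, 7, 10)
  grp <- rep(c("GE", "FE"), each = 4)
  # same slope in both groups -> b3 = 0
  same <- cm_from_edge(0.1 + 0.05 * dur)
  res0 <- interaction_model(same, grp, dur)
  expect_equal(res0$statistic[res0$i == 1 & res0$j == 2], 0,
               tolerance = 1e-12)
  # GE slope +0.5, FE slope -0.5 -> b3 = -1.0 (GE = 0, FE = 1 coding;
  # factor levels sort FE first, so recode to keep GE the reference)
  vals <- ifelse(grp == "GE", 0.5 * dur, -0.5 * dur)
  opp <- cm_from_edge(vals)
  res1 <- interaction_model(opp, factor(grp, levels = c("GE", "FE")), dur)
  expect_equal(res1$statistic[res1$i == 1 & res1$j == 2], -1,
               tolerance = 1e-10)
  expect_match(attr(res1, "coding"), "GE=0")
  expect_error(interaction_model(same, rep("GE", 8), dur), "two")
})

test_that("cohort balance reproduces matched-marginal statistics", {
  ph <- data.frame(
    group = rep(c("GE", "FE", "HC"), each = 114),
    sex = rep(rep(c("M", "F"), c(75, 39)), 3),
    age = rep(seq(18, 55, length.out = 114), 3),
    duration_years = c(seq(1, 15, length.out = 114),
                       seq(2, 16, length.out = 114), rep(NA, 114)),
    seizure_freq_per_month = c(seq(1, 3, length.out = 114),
                               seq(1.2, 3.4, length.out = 114), rep(NA, 114))
  )
  bal <- cohort_balance(ph)
  # identical 75/39 sex counts in all groups: chi-square exactly 0
  expect_equal(bal$sex_chisq, 0, tolerance = 1e-12)
  expect_equal(bal$sex_p, 1)
  # identical age vectors: F = 0
  expect_equal(bal$age_f, 0, tolerance = 1e-12)
  expect_true(is.finite(bal$duration_t))
})

test_that("ANOVA F matches the explicit sums-of-squares oracle", {
  set.seed(8)
  ph <- data.frame(group = rep(c("A", "B", "C"), each = 20),
                   sex = "M", age = rnorm(60, 30, 5),
                   duration_years = NA_real_,
                   seizure_freq_per_month = NA_real_)
  ph$duration_years[ph$group != "C"] <- runif(40, 1, 10)
  ph$seizure_freq_per_month[ph$group != "C"] <- runif(40, 1, 4)
  bal <- cohort_balance(ph)
  gm <- mean(ph$age)
  ss_between <- sum(tapply(ph$age, ph$group, function(v)
    length(v) * (mean(v) - gm)^2))
  ss_within <- sum(tapply(ph$age, ph$group, function(v)
    sum((v - mean(v))^2)))
  f_oracle <- (ss_between / 2) / (ss_within / 57)
  expect_equal(bal$age_f, f_oracle, tolerance = 1e-10)
})
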