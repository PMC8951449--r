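test_that("parcel means match the brute-force mean oracle", {
  cfg <- small_config(seed = 3)
  coh <- generate_cohort(cfg)
  s <- coh$subjects[[1]]$series
  sig <- parcel_mean_signals(s, coh$atlas)
  expect_equal(dim(sig), c(cfg$n_volumes, 5))
  x <- series_matrix(s)
  for (lab in 1:5) {
    vox <- which(coh$atlas$cortex == lab)
    oracle <- apply(x[, vox, drop = FALSE], 1, mean)
    expect_equal(unname(sig[, lab]), oracle, tolerance = 1e-12)
  }
})

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(101)
  nt <- 80
  sig <- matrix(rnorm(nt * 5), nt, 5)
  x <- matrix(rnorm(nt * 12), nt, 12)
  s <- series4d(array(t(x), dim = c(12, 1, 1, nt)), 2)
  mask <- array(TRUE, c(12, 1, 1))
  map <- voxel_partial_wta(s, mask, sig)
  for (c_idx in 1:5) {
    z <- cbind(1, sig[, -c_idx])
    rz <- function(v) lm.fit(z, v)$residuals
    rs <- rz(sig[, c_idx])
    oracle <- apply(x, 2, function(v) cor(rz(v), rs))
    expect_equal(unname(map$coefs[, c_idx]), oracle, tolerance = 1e-10)
  }
})

test_that("partialing removes correlation inherited through a covariate", {
  set.seed(7)
  nt <- 400
  s1 <- rnorm(nt)
  s3 <- 0.8 * s1 + 0.6 * rnorm(nt)       # s3 correlated with s1
  sig <- cbind(s1, rnorm(nt), s3, rnorm(nt), rnorm(nt))
  xv <- s1 + 0.1 * rnorm(nt)             # voxel driven by s1 only
  expect_gt(abs(cor(xv, s3)), 0.4)       # plain correlation is inflated
  s <- series4d(array(xv, dim = c(1, 1, 1, nt)), 2)
  map <- voxel_partial_wta(s, array(TRUE, c(1, 1, 1)), sig)
  expect_lt(abs(map$coefs[1, 3]), 0.1)   # partial r ~ 0 given s1
  expect_equal(map$labels[1], 1L)
})

test_that("a planted copy of a latent recovers its label with r near 1", {
  set.seed(23)
  nt <- 100
  sig <- qr.Q(qr(matrix(rnorm(nt * 5), nt, 5)))  # orthogonal latents
  xv <- sig[, 2]
  s <- series4d(array(xv, dim = c(1, 1, 1, nt)), 2)
  map <- voxel_partial_wta(s, array(TRUE, c(1, 1, 1)), sig)
  expect_equal(map$labels[1], 2L)
  expect_gt(map$coefs[1, 2], 0.999)
})

test_that("zero-variance voxels are unassigned with NA coefficients", {
  set.seed(4)
  nt <- 60
  x <- cbind(rep(1, nt), rnorm(nt))
  s <- series4d(array(t(x), dim = c(2, 1, 1, nt)), 2)
  sig <- matrix(rnorm(nt * 5), nt, 5)
  map <- suppressWarnings(voxel_partial_wta(s, array(TRUE, c(2, 1, 1)), sig))
  expect_true(is.na(map$labels[1]))
  expect_true(all(is.na(map$coefs[1, ])))
  expect_false(is.na(map$labels[2]))
})

test_that("WTA labels survive any increasing transform of coefficients", {
  fx <- small_processed_cohort()
  map <- fx$maps[[1]]$striatum
  trans <- cstcnet:::wta_from_coefs(tanh(3 * map$coefs + 0.2))
  expect_identical(trans, map$labels)
})

test_that("degenerate single-window dynamic WTA equals the static map", {
  fx <- small_processed_cohort()
  pp <- fx$preprocessed[[1]]
  atlas <- fx$cohort$atlas
  sig <- parcel_mean_signals(pp$series, atlas)
  nt <- dim(pp$series)[4]
  st <- voxel_partial_wta(pp$series, atlas$thalamus, sig, "thalamus")
  dyn <- windowed_voxel_wta(pp$series, atlas$thalamus, sig,
                            window_tr = nt, step_tr = 5, "thalamus")
  expect_equal(dyn$coefs, st$coefs, tolerance = 1e-12)
  expect_identical(dyn$labels, st$labels)
  expect_error(windowed_voxel_wta(pp$series, atlas$thalamus, sig,
                                  window_tr = nt + 1, step_tr = 5), "fit")
})

test_that("stationary data give near-identical static and dynamic maps", {
  fx <- small_processed_cohort()
  pp <- fx$preprocessed[[1]]
  atlas <- fx$cohort$atlas
  sig <- parcel_mean_signals(pp$series, atlas)
  st <- voxel_partial_wta(pp$series, atlas$striatum, sig, "striatum")
  dyn <- windowed_voxel_wta(pp$series, atlas$striatum, sig,
                            window_tr = 30, step_tr = 5, "striatum")
  for (lab in 1:5) expect_gte(dice(st, dyn, lab), 0.9)
})

test_that("group map averages coefficients and recovers planted labels", {
  fx <- small_processed_cohort()
  maps <- lapply(fx$maps, `[[`, "striatum")
  gm <- group_wta(maps)
  truth <- fx$cohort$truth$voxel_labels$striatum[gm$voxels]
  expect_gte(mean(gm$labels == truth, na.rm = TRUE), 0.99)
  # identical inputs reproduce the input
  same <- group_wta(list(maps[[1]], maps[[1]]))
  expect_identical(same$labels, maps[[1]]$labels)
  expect_equal(same$coefs, maps[[1]]$coefs, tolerance = 1e-12)
  # mixed structures refuse
  expect_error(group_wta(list(maps[[1]], fx$maps[[1]]$thalamus)),
               "structures")
})

test_that("opposing coefficients resolve by the mean with low-label ties", {
  a <- fake_wta_map(c(1L, 2L)); b <- fake_wta_map(c(3L, 2L))
  gm <- group_wta(list(a, b))
  # voxel 1: mean coefs put labels 1 and 3 at 0.5 each -> tie -> label 1
  expect_equal(gm$labels[1], 1L)
  expect_equal(gm$labels[2], 2L)
})

test_that("Dice matches hand computation and is symmetric and bounded", {
  a <- fake_wta_map(c(1L, 1L, 1L, 2L, 2L))
  b <- fake_wta_map(c(2L, 1L, 1L, 1L, 2L))
  # label 1: A = {1,2,3}, B = {2,3,4} -> 2*2/(3+3)
  expect_equal(dice(a, b, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(dice(a, b, 1), dice(b, a, 1))
  expect_equal(dice(a, a, 1), 1)
  expect_equal(dice(a, a, 2), 1)
  disj <- fake_wta_map(c(2L, 2L, 2L, 1L, 1L))
  aa <- fake_wta_map(c(1L, 1L, 1L, 2L, 2L))
  expect_equal(dice(aa, disj, 1), 0)
  expect_error(dice(a, b, 5), "absent")
  for (lab in 1:2) {
    d <- dice(a, b, lab)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("Dice profile standardizes against a reference and flags absences", {
  a <- fake_wta_map(c(1L, 1L, 2L, 2L, NA))
  b <- fake_wta_map(c(1L, 2L, 2L, 2L, NA))
  prof <- dice_profile(a, b)
  # a profile standardized by itself is 1 wherever defined
  self <- dice_profile(a, b, reference = prof)
  expect_equal(self$standardized[1:2], c(1, 1), tolerance = 1e-12)
  # label absent from both maps is NA, not 0
  expect_true(all(is.na(prof$dice[prof$label %in% 3:5])))
  ref <- data.frame(label = 1:5, dice = c(0.8, 0.8, 1, 1, 1))
  std <- dice_profile(a, b, reference = ref)
  expect_equal(std$standardized[1], dice(a, b, 1) / 0.8, tolerance = 1e-12)
  bad_ref <- data.frame(label = 1:5, dice = c(0, 1, 1, 1, 1))
  expect_error(dice_profile(a, b, reference = bad_ref), "undefined")
})
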