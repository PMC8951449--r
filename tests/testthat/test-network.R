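test_that("the ROI set has 20 disjoint ROIs partitioning each structure", {
  fx <- small_processed_cohort()
  rois <- fx$rois
  expect_length(rois, 20)
  expect_identical(names(rois), roi_names())
  atlas <- fx$cohort$atlas
  for (s in subcortical_structures()) {
    vox <- unlist(lapply(rois[paste(s, cortical_systems(), sep = "_")],
                         `[[`, "voxels"))
    expect_false(any(duplicated(vox)))
    unassigned <- sum(is.na(fx$hc_maps[[s]]$labels))
    expect_equal(length(vox), sum(atlas[[s]]) - unassigned)
  }
})

test_that("a group map missing a label names the empty subregion", {
  fx <- small_processed_cohort()
  broken <- fx$hc_maps
  m <- broken$thalamus
  m$labels[m$labels == 5] <- 4L
  broken$thalamus <- m
  expect_error(define_rois(broken, fx$cohort$atlas), "thalamus, 5")
  dyn <- fx$hc_maps
  dyn$striatum$mode <- "dynamic-mean"
  expect_error(define_rois(dyn, fx$cohort$atlas), "static")
})

test_that("ROI mean signals match the brute-force oracle with fixed order", {
  fx <- small_processed_cohort()
  pp <- fx$preprocessed[[2]]
  sig <- roi_mean_signals(pp$series, fx$rois)
  expect_identical(colnames(sig), roi_names())
  x <- series_matrix(pp$series)
  for (k in c(1, 7, 20)) {
    oracle <- apply(x[, fx$rois[[k]]$voxels, drop = FALSE], 1, mean)
    expect_equal(unname(sig[, k]), oracle, tolerance = 1e-12)
  }
  sig2 <- roi_mean_signals(pp$series, fx$rois)
  expect_identical(sig, sig2)
})

test_that("Fisher transform is odd, monotone, and atanh(0.5) = 0.5493", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)))
})

test_that("null partial correlations of independent series stay small", {
  set.seed(202)
  sig <- matrix(rnorm(240 * 20), 240, 20)
  colnames(sig) <- roi_names()
  z <- static_network(sig)
  expect_true(isSymmetric(unclass(z), tol = 1e-12))
  expect_equal(unname(diag(z)), rep(0, 20))
  off <- unclass(z)[upper.tri(z)]
  # null partial z ~ N(0, ~1/sqrt(T)); the bulk stays well below 0.2
  expect_lt(quantile(abs(off), 0.95), 0.15)
  expect_lt(max(abs(off)), 0.3)
})

test_that("static network recovers a planted precision pattern", {
  set.seed(77)
  p <- 20
  prec <- diag(p)
  planted <- rbind(c(1, 6), c(2, 11), c(3, 16), c(7, 12), c(8, 20))
  for (k in seq_len(nrow(planted))) {
    prec[planted[k, 1], planted[k, 2]] <- -0.4
    prec[planted[k, 2], planted[k, 1]] <- -0.4
  }
  sigma <- solve(prec)
  l <- chol(sigma)
  x <- matrix(rnorm(240 * p), 240, p) %*% l
  colnames(x) <- roi_names()
  z <- static_network(x)
  # planted partial correlations are positive (-prec off-diagonal > 0)
  signs <- apply(planted, 1, function(ij) unclass(z)[ij[1], ij[2]] > 0.2)
  expect_gte(mean(signs), 0.95)
  null_mask <- upper.tri(prec) & prec == 0
  expect_lt(mean(abs(unclass(z)[null_mask])), 0.1)
})

test_that("singular covariance errors and shrinkage rescues it", {
  sig <- matrix(rnorm(50 * 20), 50, 20)
  sig[, 2] <- sig[, 1]                    # exact collinearity
  colnames(sig) <- roi_names()
  expect_error(static_network(sig), "shrinkage")
  z <- static_network(sig, shrinkage = 0.1)
  expect_true(all(is.finite(unclass(z))))
})

test_that("sliding-window arithmetic matches floor((T-w)/s)+1", {
  w <- sliding_windows(240, 50, 5)
  expect_equal(nrow(w), 39)
  expect_equal(w$start[1], 1); expect_equal(w$end[1], 50)
  expect_equal(w$start[39], 191); expect_equal(w$end[39], 240)
  expect_equal(nrow(sliding_windows(240, 30, 5)), 43)
  expect_equal(nrow(sliding_windows(240, 60, 5)), 37)
  expect_equal(nrow(sliding_windows(240, 100, 5)), 29)
  expect_equal(nrow(sliding_windows(240, 240, 5)), 1)
  expect_error(sliding_windows(240, 241, 5), "fit")
})

test_that("stationary window matrices fluctuate around the static Pearson", {
  set.seed(5)
  n <- 240
  base <- matrix(rnorm(n * 3), n, 3)
  sig <- cbind(base[, 1], 0.7 * base[, 1] + 0.7 * base[, 2], base[, 3])
  dyn <- dynamic_network(sig, 50, 5)
  expect_length(dyn$matrices, 39)
  mean_w <- dfc_mean(dyn)
  full_z <- fisher_z(cor(sig))
  expect_lt(max(abs(unclass(mean_w)[upper.tri(mean_w)] -
                    full_z[upper.tri(full_z)])), 0.15)
})

test_that("identical ROIs hit the z clip in every window", {
  set.seed(9)
  v <- rnorm(100)
  sig <- cbind(v, v, rnorm(100))
  dyn <- dynamic_network(sig, 40, 10)
  clip_z <- atanh(1 - 1e-6)
  for (m in dyn$matrices) expect_equal(unclass(m)[1, 2], clip_z)
})

test_that("dFC variability matches the two-pass SD oracle", {
  set.seed(44)
  sig <- matrix(rnorm(120 * 4), 120, 4)
  dyn <- dynamic_network(sig, 30, 10)
  v <- dfc_variability(dyn)
  ws <- sapply(dyn$matrices, function(m) unclass(m)[1, 3])
  oracle <- sqrt(sum((ws - mean(ws))^2) / (length(ws) - 1))
  expect_equal(unclass(v)[1, 3], oracle, tolerance = 1e-12)
  expect_equal(unname(diag(v)), rep(0, 4))
  # identical window matrices -> all-zero variability
  same <- dyn; same$matrices <- rep(dyn$matrices[1], 5)
  expect_equal(max(abs(unclass(dfc_variability(same)))), 0)
  one <- dyn; one$matrices <- dyn$matrices[1]
  expect_error(dfc_variability(one), "2 windows")
})

test_that("a coupling switch inflates the planted edge's variability", {
  set.seed(13)
  n <- 240
  e <- rnorm(n)
  gate <- rep(c(0, 1), each = n / 2)
  a <- rnorm(n) + sqrt(0.8) * gate * e
  b <- rnorm(n) + sqrt(0.8) * gate * e
  c1 <- rnorm(n); c2 <- rnorm(n)
  v <- dfc_variability(dynamic_network(cbind(a, b, c1, c2), 50, 5))
  expect_gt(unclass(v)[1, 2], unclass(v)[3, 4])
})

test_that("feature flattening yields 400/400/800 named entries", {
  a <- random_cm(1); b <- random_cm(2, kind = "dfc_sd_z")
  f <- flatten_features(a)
  expect_length(f, 400)
  expect_equal(unname(f[2]), unclass(a)[1, 2])   # row-major order
  ft_s <- feature_table(list(a, a), NULL, c(1, -1), "static")
  ft_d <- feature_table(NULL, list(b, b), c(1, -1), "dynamic")
  ft_c <- feature_table(list(a, a), list(b, b), c(1, -1), "combined")
  expect_equal(ncol(ft_s$x), 400)
  expect_equal(ncol(ft_d$x), 400)
  expect_equal(ncol(ft_c$x), 800)
  expect_error(feature_table(list(a), NULL, c(1, 2), "static"), "label")
})

test_that("connectivity matrices round-trip through TSV exactly", {
  m <- random_cm(31)
  f <- file.path(tempdir(), "cm.tsv")
  cstcnet:::write_matrix_tsv(m, f)
  back <- utils::read.delim(f, check.names = FALSE)
  m2 <- as.matrix(back[, -1])
  dimnames(m2) <- dimnames(m)
  expect_equal(m2, unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
  unlink(f)
})
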