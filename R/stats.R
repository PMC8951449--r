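#' Index table of the unique off-diagonal edges
#'
#' The 20-node network has `choose(20, 2) = 190` unique edges; every
#' edgewise routine operates on these, in a fixed column-major upper-triangle
#' order.
#'
#' @param n number of nodes (default 20).
#' @return data frame with node indices `i < j` and the `edge` label.
#' @export
edge_index <- function(n = 20L) {
  rn <- if (n == 20L) roi_names() else as.character(seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             edge = paste(rn[idx[, 1]], rn[idx[, 2]], sep = ".."))
}

edge_values <- function(matrices) {
  # subjects x edges matrix of unique off-diagonal entries
  n <- nrow(matrices[[1]])
  ut <- upper.tri(matrix(0, n, n))
  t(vapply(matrices, function(m) unclass(m)[ut], numeric(sum(ut))))
}

new_edgewise_stats <- function(ei, statistic, p, q_threshold, stat_name) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  out <- data.frame(ei, statistic = statistic, p = p, q = q,
                    significant = !is.na(q) & q < q_threshold)
  attr(out, "stat_name") <- stat_name
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("edgewise_stats", class(out))
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity
#' (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values vector of raw p-values in `[0, 1]` (NA allowed).
#' @return adjusted q-values, same length.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Edgewise two-sample t-test between groups
#'
#' Pooled-variance two-sample t per unique edge, with BH-FDR over the 190
#' raw p-values and a significance mask at `q < q_threshold`. Edges with
#' zero within-group variance in both groups get `p = NA` and are excluded
#' from the FDR family.
#'
#' @param group_a,group_b lists of `connectivity_matrix` objects of the same
#'   kind (one per subject).
#' @param q_threshold FDR threshold (default 0.05).
#' @param welch use Welch's unequal-variance t instead of the pooled test.
#' @return data frame of class `edgewise_stats` with per-edge `statistic`
#'   (t), `p`, `q`, `significant`.
#' @export
edgewise_ttest <- function(group_a, group_b, q_threshold = 0.05,
                           welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 subjects per group")
  ka <- matrix_kind(group_a[[1]]); kb <- matrix_kind(group_b[[1]])
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb))
    stop("matrix kinds differ between groups: ", ka, " vs ", kb)
  xa <- edge_values(group_a); xb <- edge_values(group_b)
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  }
  t_stat <- (ma - mb) / se
  t_stat[se == 0] <- NA_real_
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  new_edgewise_stats(edge_index(nrow(group_a[[1]])), t_stat, p, q_threshold,
                     "t")
}

#' Edgewise Pearson correlation with disease duration
#'
#' @param matrices per-subject `connectivity_matrix` list (patients).
#' @param durations disease duration in years, one per subject.
#' @param q_threshold FDR threshold (default 0.05).
#' @return `edgewise_stats` with per-edge Pearson `statistic` (r), `p`,
#'   `q`, `significant`.
#' @export
edgewise_duration_correlation <- function(matrices, durations,
                                          q_threshold = 0.05) {
  n <- length(matrices)
  if (n < 4) stop("need at least 4 subjects")
  if (!all(is.finite(durations)) || length(durations) != n)
    stop("durations must be finite, one per subject")
  if (stats::sd(durations) == 0)
    stop("durations are constant; correlation undefined")
  z <- edge_values(matrices)
  # zero-variance edges are flagged NA below; silence cor()'s sd warning
  r <- drop(suppressWarnings(stats::cor(durations, z)))
  sd0 <- apply(z, 2, stats::sd) == 0
  r[sd0] <- NA_real_
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  new_edgewise_stats(edge_index(nrow(matrices[[1]])), r, p, q_threshold, "r")
}

#' Edgewise group x duration interaction model
#'
#' Ordinary least squares per edge:
#' `z = b0 + b1 group + b2 duration + b3 (group x duration)`, with group
#' coded 0 for the first level (GE) and 1 for the second (FE); the reported
#' statistic is the t-test on the interaction coefficient b3.
#'
#' @param matrices per-subject `connectivity_matrix` list over both patient
#'   groups.
#' @param groups group label per subject (exactly two distinct values; the
#'   first level in sort order or factor order is coded 0).
#' @param durations duration in years per subject.
#' @param q_threshold FDR threshold (default 0.05).
#' @return `edgewise_stats` with per-edge `statistic` (b3), `t`, `p`, `q`,
#'   `significant`; the group coding is recorded in the `coding` attribute.
#' @export
interaction_model <- function(matrices, groups, durations,
                              q_threshold = 0.05) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("need exactly two patient groups")
  if (any(table(g) < 3)) stop("need at least 3 subjects per group")
  g01 <- as.numeric(g) - 1
  d <- cbind(1, g01, durations, g01 * durations)
  colnames(d) <- c("intercept", "group", "duration", "group_x_duration")
  qrd <- qr(d)
  if (qrd$rank < 4) stop("interaction design is rank deficient")
  z <- edge_values(matrices)
  n <- nrow(z)
  beta <- qr.coef(qrd, z)
  res <- z - d %*% beta
  df <- n - 4
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrd))
  se_b3 <- sqrt(sigma2 * xtx_inv[4, 4])
  b3 <- beta[4, ]
  t_stat <- b3 / se_b3
  t_stat[se_b3 == 0] <- NA_real_
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  out <- new_edgewise_stats(edge_index(nrow(matrices[[1]])), b3, p,
                            q_threshold, "b3")
  out$t <- t_stat
  attr(out, "coding") <- paste0(levels(g)[1], "=0, ", levels(g)[2], "=1")
  out
}

#' Cohort balance statistics
#'
#' One-way ANOVA on age across the three groups, Pearson chi-square (no
#' continuity correction) on the sex x group table, and pooled two-sample
#' t-tests on duration and seizure frequency between the two patient groups.
#'
#' @param phenotypes subject table with columns `group`, `sex`, `age`,
#'   `duration_years`, `seizure_freq_per_month`.
#' @return list of class `cohort_balance` with `age_f`, `age_p`,
#'   `sex_chisq`, `sex_p`, `duration_t`, `duration_p`, `freq_t`, `freq_p`.
#' @export
cohort_balance <- function(phenotypes) {
  ph <- phenotypes
  if (any(table(ph$group) == 0) || !nrow(ph)) stop("empty group")
  fit <- stats::aov(age ~ group, data = transform(ph, group = factor(group)))
  an <- summary(fit)[[1]]
  chi <- suppressWarnings(
    stats::chisq.test(table(ph$sex, ph$group), correct = FALSE))
  pat <- ph[!is.na(ph$duration_years), , drop = FALSE]
  tt <- function(v) {
    gs <- unique(pat$group)
    if (length(gs) != 2) return(list(statistic = NA_real_, p.value = NA_real_))
    tryCatch(
      stats::t.test(v[pat$group == gs[1]], v[pat$group == gs[2]],
                    var.equal = TRUE),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  }
  td <- tt(pat$duration_years)
  tf <- tt(pat$seizure_freq_per_month)
  structure(list(
    age_f = an[["F value"]][1], age_p = an[["Pr(>F)"]][1],
    sex_chisq = unname(chi$statistic), sex_p = unname(chi$p.value),
    duration_t = unname(td$statistic), duration_p = unname(td$p.value),
    freq_t = unname(tf$statistic), freq_p = unname(tf$p.value)
  ), class = "cohort_balance")
}

#' @export
print.cohort_balance <- function(x, ...) {
  cat("<cohort_balance>\n")
  cat(sprintf("  age ANOVA:       F = %.4g, p = %.4g\n", x$age_f, x$age_p))
  cat(sprintf("  sex chi-square:  X2 = %.4g, p = %.4g\n", x$sex_chisq, x$sex_p))
  cat(sprintf("  duration t-test: t = %.4g, p = %.4g\n", x$duration_t, x$duration_p))
  cat(sprintf("  frequency t-test:t = %.4g, p = %.4g\n", x$freq_t, x$freq_p))
  invisible(x)
}
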