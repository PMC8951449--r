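#' Split a cohort into two matched halves
#'
#' Within each group, subjects are stratified by sex and sorted by age
#' (ties shuffled with `seed`), then dealt alternately into the two halves,
#' continuing the alternation across sex strata so the half sizes differ by
#' at most one. Balance of the resulting split is reported as an age t-test
#' and a sex chi-square between the halves.
#'
#' @param phenotypes subject table (`id`, `group`, `sex`, `age`, ...).
#' @param seed integer seed for tie-shuffling.
#' @return object of class `split_report`: `assignment` (1 or 2 per row of
#'   `phenotypes`), and per-group `balance` (age t p-value, sex chi-square
#'   p-value, sizes, female counts).
#' @export
split_half <- function(phenotypes, seed = 1L) {
  ph <- phenotypes
  set.seed(as.integer(seed))
  assignment <- integer(nrow(ph))
  balance <- list()
  for (g in unique(ph$group)) {
    rows <- which(ph$group == g)
    if (length(rows) < 4) stop("group ", g, " too small to split")
    parity <- 0L
    for (sx in unique(ph$sex[rows])) {
      sr <- rows[ph$sex[rows] == sx]
      sr <- sr[sample(length(sr))]         # shuffle ties
      sr <- sr[order(ph$age[sr])]
      assignment[sr] <- ((seq_along(sr) - 1L + parity) %% 2L) + 1L
      parity <- (parity + length(sr)) %% 2L
    }
    h1 <- rows[assignment[rows] == 1L]; h2 <- rows[assignment[rows] == 2L]
    age_p <- tryCatch(
      stats::t.test(ph$age[h1], ph$age[h2], var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    sex_tab <- table(ph$sex[rows], assignment[rows])
    sex_p <- if (nrow(sex_tab) > 1)
      suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE)$p.value)
    else NA_real_
    balance[[g]] <- list(
      n = c(length(h1), length(h2)),
      females = c(sum(ph$sex[h1] == "F"), sum(ph$sex[h2] == "F")),
      age_p = age_p, sex_p = sex_p)
  }
  structure(list(assignment = assignment, balance = balance,
                 phenotypes = ph), class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat("<split_report>\n")
  for (g in names(x$balance)) {
    b <- x$balance[[g]]
    cat(sprintf("  %s: n = %d/%d, females %d/%d, age p = %.3f, sex p = %s\n",
                g, b$n[1], b$n[2], b$females[1], b$females[2], b$age_p,
                formatC(b$sex_p, digits = 3, format = "g")))
  }
  invisible(x)
}

#' Pattern correlation between two group-mean connectivity matrices
#'
#' Pearson correlation (with its p-value) over the 190 unique off-diagonal
#' entries of two matrices of the same kind.
#'
#' @param mean_a,mean_b `connectivity_matrix` objects of identical kind and
#'   labels.
#' @return list with `r` and `p`.
#' @export
pattern_correlation <- function(mean_a, mean_b) {
  ka <- matrix_kind(mean_a); kb <- matrix_kind(mean_b)
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb))
    stop("matrix kinds differ: ", ka, " vs ", kb)
  if (!identical(dimnames(mean_a), dimnames(mean_b)))
    stop("ROI labels differ between matrices")
  ut <- upper.tri(mean_a)
  ct <- stats::cor.test(unclass(mean_a)[ut], unclass(mean_b)[ut])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Entrywise mean of a list of connectivity matrices
#' @param matrices list of `connectivity_matrix` objects of one kind.
#' @return a `connectivity_matrix` of the same kind.
#' @export
group_mean_matrix <- function(matrices) {
  m <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  new_connectivity_matrix(m, matrix_kind(matrices[[1]]))
}

#' Sliding-window-size sensitivity sweep
#'
#' Recomputes the group-mean dynamic-connectivity variability matrix for a
#' set of window sizes and reports the pattern correlation of each against
#' the reference window size.
#'
#' @param roi_signals_list list of per-subject timepoints x 20 ROI signal
#'   matrices.
#' @param window_sizes window lengths in TRs to evaluate (default
#'   `c(30, 60, 100)`).
#' @param step_tr sliding step in TRs (default 5).
#' @param reference_tr reference window length (default 50).
#' @return data frame: `window_tr`, `n_windows`, `r`, `p` (correlation
#'   against the reference variability pattern; the reference row has
#'   `r = 1`).
#' @export
window_sweep <- function(roi_signals_list, window_sizes = c(30, 60, 100),
                         step_tr = 5L, reference_tr = 50L) {
  var_for <- function(w) {
    group_mean_matrix(lapply(roi_signals_list, function(sig)
      dfc_variability(dynamic_network(sig, w, step_tr))))
  }
  nt <- nrow(roi_signals_list[[1]])
  ref <- var_for(reference_tr)
  all_w <- c(reference_tr, setdiff(window_sizes, reference_tr))
  rows <- lapply(all_w, function(w) {
    m <- if (w == reference_tr) ref else var_for(w)
    pc <- pattern_correlation(ref, m)
    data.frame(window_tr = w,
               n_windows = nrow(sliding_windows(nt, w, step_tr)),
               r = pc$r, p = pc$p)
  })
  do.call(rbind, rows)
}
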