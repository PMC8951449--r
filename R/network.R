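#' Names of the 20 network ROIs in canonical order
#'
#' Fixed ordering used by every matrix and feature vector: the 5 cortical
#' systems, then the 5 winner-take-all subregions of the striatum, thalamus
#' and cerebellum (each named after its affiliated cortical system).
#'
#' @return character vector of length 20.
#' @export
roi_names <- function() {
  as.vector(vapply(
    c("cortex", subcortical_structures()),
    function(s) paste(s, cortical_systems(), sep = "_"),
    character(5)
  ))
}

#' Define the 20-ROI set from healthy-control group maps
#'
#' The 5 cortical ROIs come from the atlas; the 15 subcortical ROIs are the
#' winner-take-all subregions of the striatum, thalamus and cerebellum in
#' the healthy-control static group maps. The same ROI set is reused for
#' every group.
#'
#' @param hc_group_maps named list with elements `striatum`, `thalamus`,
#'   `cerebellum`: static-mode group `wta_map`s from the HC group.
#' @param atlas an [atlas_bundle].
#' @return object of class `roi_set`: a named list of 20 ROIs, each with
#'   `name`, `structure`, `system`, `voxels` (linear indices).
#' @export
define_rois <- function(hc_group_maps, atlas) {
  for (s in subcortical_structures()) {
    if (is.null(hc_group_maps[[s]]))
      stop("missing healthy-control group map for ", s)
    if (!grepl("static", hc_group_maps[[s]]$mode))
      stop("group map for ", s, " is not static-mode")
  }
  rois <- list()
  for (lab in 1:5) {
    nm <- paste("cortex", cortical_systems()[lab], sep = "_")
    rois[[nm]] <- list(name = nm, structure = "cortex",
                       system = cortical_systems()[lab],
                       voxels = which(atlas$cortex == lab))
  }
  missing <- character()
  for (s in subcortical_structures()) {
    m <- hc_group_maps[[s]]
    for (lab in 1:5) {
      nm <- paste(s, cortical_systems()[lab], sep = "_")
      vox <- m$voxels[!is.na(m$labels) & m$labels == lab]
      if (!length(vox)) missing <- c(missing, paste0("(", s, ", ", lab, ")"))
      rois[[nm]] <- list(name = nm, structure = s,
                         system = cortical_systems()[lab], voxels = vox)
    }
  }
  if (length(missing))
    stop("empty winner-take-all subregion(s): ",
         paste(missing, collapse = ", "))
  stopifnot(identical(names(rois), roi_names()))
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  sizes <- vapply(x, function(r) length(r$voxels), integer(1))
  cat("<roi_set> 20 ROIs\n")
  print(sizes)
  invisible(x)
}

#' Mean time series of the 20 network ROIs
#'
#' @param series a preprocessed [series4d].
#' @param rois a [define_rois()] ROI set.
#' @return numeric matrix timepoints x 20 in [roi_names()] order.
#' @export
roi_mean_signals <- function(series, rois) {
  x <- series_matrix(series)
  out <- vapply(rois, function(r) {
    if (!length(r$voxels)) stop("ROI ", r$name, " is empty")
    rowMeans(x[, r$voxels, drop = FALSE])
  }, numeric(n_timepoints(series)))
  colnames(out) <- names(rois)
  out
}

new_connectivity_matrix <- function(m, kind) {
  if (is.null(dimnames(m)) && nrow(m) == 20L)
    dimnames(m) <- list(roi_names(), roi_names())
  stopifnot(nrow(m) == ncol(m))
  attr(m, "kind") <- kind
  class(m) <- c("connectivity_matrix", class(m))
  m
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %dx%d, kind = %s\n",
              nrow(x), ncol(x), attr(x, "kind")))
  m <- unclass(x)
  attr(m, "kind") <- NULL
  print(utils::head(round(m[, 1:min(6, ncol(m))], 3)))
  invisible(x)
}

matrix_kind <- function(m) attr(m, "kind")

#' Fisher r-to-z transform with clipping
#'
#' `z = atanh(r)` after clipping `|r|` at `1 - 1e-6` so the transform stays
#' finite for numerically perfect correlations.
#'
#' @param r correlation value(s).
#' @param clip largest admissible `|r|`.
#' @return z value(s).
#' @export
fisher_z <- function(r, clip = 1 - 1e-6) atanh(pmin(pmax(r, -clip), clip))

#' Static partial-correlation network
#'
#' Pairwise partial correlations among the 20 ROI series, each pair
#' conditioned on the remaining 18 series, computed from the inverse of the
#' 20x20 covariance matrix; coefficients are clipped and Fisher
#' z-transformed; the diagonal is fixed at 0.
#'
#' @param roi_signals timepoints x 20 matrix from [roi_mean_signals()].
#' @param shrinkage ridge weight in `[0, 1)` mixing the sample covariance
#'   with its diagonal mean, for ill-conditioned inputs (default 0).
#' @return a `connectivity_matrix` of kind `"static_z"`.
#' @export
static_network <- function(roi_signals, shrinkage = 0) {
  p <- ncol(roi_signals)
  if (nrow(roi_signals) <= p + 1)
    stop("need more timepoints than ROIs + 1 for full partial correlation")
  s <- stats::cov(roi_signals)
  if (shrinkage > 0)
    s <- (1 - shrinkage) * s + shrinkage * mean(diag(s)) * diag(p)
  prec <- tryCatch(solve(s), error = function(e)
    stop("ROI covariance is singular; retry with a positive `shrinkage`"))
  r <- -stats::cov2cor(prec)
  diag(r) <- 0
  z <- fisher_z(r)
  dimnames(z) <- dimnames(s)
  new_connectivity_matrix(z, "static_z")
}

#' Sliding-window index ranges
#'
#' Windows of `window_tr` consecutive samples advanced by `step_tr`; the
#' count is `floor((T - window_tr) / step_tr) + 1`.
#'
#' @param n_timepoints series length T.
#' @param window_tr window length in TRs.
#' @param step_tr step in TRs.
#' @return data frame with 1-based inclusive `start` and `end` per window.
#' @export
sliding_windows <- function(n_timepoints, window_tr, step_tr) {
  if (window_tr <= 0 || window_tr > n_timepoints)
    stop("window of ", window_tr, " TRs does not fit ", n_timepoints,
         " timepoints")
  if (step_tr < 1) stop("step must be >= 1 TR")
  n_win <- floor((n_timepoints - window_tr) / step_tr) + 1
  start <- (seq_len(n_win) - 1L) * step_tr + 1L
  data.frame(start = start, end = start + window_tr - 1L)
}

#' Sliding-window dynamic connectivity
#'
#' Per-window pairwise Pearson correlation of the 20 ROI series (plain
#' correlation, not partial: a 50-sample window cannot support 18-covariate
#' partialing stably), clipped and Fisher z-transformed.
#'
#' @inheritParams static_network
#' @param window_tr,step_tr window length and step in TRs (defaults 50, 5).
#' @return object of class `dynamic_connectivity`: list with `windows`
#'   (index ranges), `matrices` (per-window z matrices), `window_tr`,
#'   `step_tr`.
#' @export
dynamic_network <- function(roi_signals, window_tr = 50L, step_tr = 5L) {
  wins <- sliding_windows(nrow(roi_signals), window_tr, step_tr)
  mats <- lapply(seq_len(nrow(wins)), function(w) {
    r <- stats::cor(roi_signals[wins$start[w]:wins$end[w], , drop = FALSE])
    diag(r) <- 0
    new_connectivity_matrix(fisher_z(r), "window_z")
  })
  structure(list(windows = wins, matrices = mats,
                 window_tr = window_tr, step_tr = step_tr),
            class = "dynamic_connectivity")
}

#' @export
print.dynamic_connectivity <- function(x, ...) {
  cat(sprintf("<dynamic_connectivity> %d windows of %d TRs, step %d\n",
              nrow(x$windows), x$window_tr, x$step_tr))
  invisible(x)
}

#' Entrywise mean of the window matrices
#' @param dyn a [dynamic_network()] result.
#' @return a `connectivity_matrix` of kind `"dfc_mean_z"`.
#' @export
dfc_mean <- function(dyn) {
  m <- Reduce(`+`, dyn$matrices) / length(dyn$matrices)
  new_connectivity_matrix(unclass(m), "dfc_mean_z")
}

#' Dynamic-connectivity variability (flexibility)
#'
#' Entrywise sample standard deviation (denominator n - 1) of the Fisher-z
#' values across sliding windows; the diagonal is fixed at 0.
#'
#' @param dyn a [dynamic_network()] result with at least 2 windows.
#' @return a `connectivity_matrix` of kind `"dfc_sd_z"`.
#' @export
dfc_variability <- function(dyn) {
  k <- length(dyn$matrices)
  if (k < 2) stop("need at least 2 windows to compute variability")
  mean_m <- Reduce(`+`, dyn$matrices) / k
  ss <- Reduce(`+`, lapply(dyn$matrices, function(m) (m - mean_m)^2))
  sd_m <- sqrt(ss / (k - 1))
  diag(sd_m) <- 0
  new_connectivity_matrix(unclass(sd_m), "dfc_sd_z")
}

#' Flatten a connectivity matrix into the 400-entry feature vector
#'
#' Row-major flattening of the full 20x20 matrix, including both symmetric
#' duplicates and the zero diagonal, reproducing the canonical static (400),
#' dynamic (400) and combined (800) feature counts.
#'
#' @param m a `connectivity_matrix`.
#' @return named numeric vector of length `nrow(m)^2`.
#' @export
flatten_features <- function(m) {
  rn <- rownames(m)
  v <- as.vector(t(unclass(m)))
  names(v) <- as.vector(t(outer(rn, rn, paste, sep = "..")))
  v
}

#' Assemble a subjects x features table for classification
#'
#' @param static_list,dynamic_list per-subject `connectivity_matrix` lists
#'   (static z and dFC variability); either may be `NULL` when not part of
#'   `feature_set`.
#' @param labels vector of +1 / -1 class labels (+1 = GE, -1 = FE by
#'   convention).
#' @param feature_set one of `"static"`, `"dynamic"`, `"combined"`.
#' @return object of class `feature_table`: list with `x` (subjects x
#'   features matrix), `y` (labels), `feature_set`.
#' @export
feature_table <- function(static_list = NULL, dynamic_list = NULL, labels,
                          feature_set = c("combined", "static", "dynamic")) {
  feature_set <- match.arg(feature_set)
  block <- function(lst, tag) {
    x <- t(vapply(lst, flatten_features, numeric(length(flatten_features(lst[[1]])))))
    colnames(x) <- paste0(tag, ".", colnames(x))
    x
  }
  x <- switch(feature_set,
    static = block(static_list, "static"),
    dynamic = block(dynamic_list, "dynamic"),
    combined = cbind(block(static_list, "static"),
                     block(dynamic_list, "dynamic"))
  )
  if (nrow(x) != length(labels)) stop("label count does not match subjects")
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 / -1")
  structure(list(x = x, y = as.integer(labels), feature_set = feature_set),
            class = "feature_table")
}
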