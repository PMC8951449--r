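#' Mean time series of the five cortical systems
#'
#' @param series a preprocessed [series4d].
#' @param atlas an [atlas_bundle] on the series grid.
#' @return numeric matrix timepoints x 5, columns named after
#'   [cortical_systems()].
#' @export
parcel_mean_signals <- function(series, atlas) {
  x <- series_matrix(series)
  out <- vapply(1:5, function(lab) {
    vox <- which(atlas$cortex == lab)
    if (!length(vox))
      stop("cortical parcel ", lab, " (", cortical_systems()[lab],
           ") is empty")
    rowMeans(x[, vox, drop = FALSE])
  }, numeric(n_timepoints(series)))
  colnames(out) <- cortical_systems()
  out
}

partial_cor_voxels <- function(x, signals) {
  # partial correlation of every column of x with each parcel signal,
  # conditioning on the other four parcel signals (plus intercept):
  # correlate the residuals of both after projecting out the covariates.
  nt <- nrow(x)
  out <- matrix(NA_real_, ncol(x), 5)
  sds <- apply(x, 2, stats::sd)
  ok <- sds > 0
  for (c_idx in 1:5) {
    z <- cbind(1, signals[, -c_idx, drop = FALSE])
    qz <- qr(z)
    rs <- qr.resid(qz, signals[, c_idx])
    if (stats::sd(rs) == 0)
      stop("parcel signal ", c_idx, " is collinear with the covariates")
    rx <- qr.resid(qz, x[, ok, drop = FALSE])
    out[ok, c_idx] <- drop(stats::cor(rs, rx))
  }
  out
}

wta_from_coefs <- function(coefs) {
  # winner = argmax of signed coefficients; ties broken by lowest label
  labels <- rep(NA_integer_, nrow(coefs))
  ok <- stats::complete.cases(coefs)
  if (any(ok)) labels[ok] <- max.col(coefs[ok, , drop = FALSE],
                                     ties.method = "first")
  labels
}

new_wta_map <- function(structure_name, voxels, labels, coefs, mode, dims) {
  colnames(coefs) <- cortical_systems()
  structure(list(structure = structure_name, voxels = voxels,
                 labels = labels, coefs = coefs, mode = mode, dims = dims),
            class = "wta_map")
}

#' @export
print.wta_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 1:5, labels = cortical_systems()))
  cat(sprintf("<wta_map> %s (%s): %d voxels, %d unassigned\n",
              x$structure, x$mode, length(x$voxels), sum(is.na(x$labels))))
  print(tab)
  invisible(x)
}

#' Winner-take-all parcellation of a subcortical structure
#'
#' For every voxel in the structure mask, computes the partial correlation
#' with each of the five cortical-system signals, conditioning on the other
#' four signals, and assigns the voxel to the system with the highest signed
#' coefficient (ties broken deterministically towards the lowest label
#' index). Voxels with zero temporal variance are left unassigned with NA
#' coefficients.
#'
#' @param series a preprocessed [series4d].
#' @param structure_mask logical 3D mask of the structure (or a structure
#'   name resolved against `atlas`).
#' @param signals timepoints x 5 matrix from [parcel_mean_signals()].
#' @param structure_name name recorded in the map.
#' @return an object of class `wta_map`: voxel indices, winning labels,
#'   the 5 partial-correlation coefficients per voxel, and the mode flag.
#' @export
voxel_partial_wta <- function(series, structure_mask, signals,
                              structure_name = "structure") {
  if (ncol(signals) != 5) stop("`signals` must have exactly 5 columns")
  nt <- n_timepoints(series)
  if (nt < 7) stop("need at least 7 timepoints for 4 covariates + intercept")
  vox <- which(structure_mask)
  if (!length(vox)) stop("structure mask is empty")
  x <- series_matrix(series, vox)
  coefs <- partial_cor_voxels(x, signals)
  new_wta_map(structure_name, vox, wta_from_coefs(coefs), coefs, "static",
              grid_dims(series))
}

#' Winner-take-all parcellation from window-averaged dynamic connectivity
#'
#' Computes the same 5-vector of partial-correlation coefficients as
#' [voxel_partial_wta()] inside each sliding window, averages the
#' coefficients across windows, and applies the winner-take-all rule to the
#' window-mean coefficients.
#'
#' @inheritParams voxel_partial_wta
#' @param window_tr,step_tr window length and step in TRs (defaults 50, 5).
#' @return a `wta_map` with mode `"dynamic-mean"`.
#' @export
windowed_voxel_wta <- function(series, structure_mask, signals,
                               window_tr = 50L, step_tr = 5L,
                               structure_name = "structure") {
  nt <- n_timepoints(series)
  wins <- sliding_windows(nt, window_tr, step_tr)
  vox <- which(structure_mask)
  if (!length(vox)) stop("structure mask is empty")
  x <- series_matrix(series, vox)
  acc <- matrix(0, length(vox), 5)
  n_ok <- matrix(0, length(vox), 5)
  for (w in seq_len(nrow(wins))) {
    idx <- wins$start[w]:wins$end[w]
    cf <- partial_cor_voxels(x[idx, , drop = FALSE],
                             signals[idx, , drop = FALSE])
    good <- !is.na(cf)
    cf[!good] <- 0
    acc <- acc + cf
    n_ok <- n_ok + good
  }
  coefs <- acc / n_ok
  coefs[n_ok == 0] <- NA_real_
  new_wta_map(structure_name, vox, wta_from_coefs(coefs), coefs,
              "dynamic-mean", grid_dims(series))
}

#' Group-level winner-take-all map
#'
#' Averages the per-voxel coefficient vectors across subjects and applies
#' the winner-take-all rule to the group-mean coefficients. Voxels
#' unassigned in a subject contribute nothing to that voxel's mean.
#'
#' @param maps list of `wta_map` objects sharing structure and geometry.
#' @return a group-level `wta_map`.
#' @export
group_wta <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  s0 <- maps[[1]]$structure
  v0 <- maps[[1]]$voxels
  for (m in maps) {
    if (!identical(m$structure, s0)) stop("maps mix structures")
    if (!identical(m$voxels, v0)) stop("maps differ in voxel geometry")
  }
  acc <- matrix(0, length(v0), 5)
  cnt <- matrix(0, length(v0), 5)
  for (m in maps) {
    good <- !is.na(m$coefs)
    cf <- m$coefs
    cf[!good] <- 0
    acc <- acc + cf
    cnt <- cnt + good
  }
  coefs <- acc / cnt
  coefs[cnt == 0] <- NA_real_
  new_wta_map(s0, v0, wta_from_coefs(coefs), coefs,
              paste0("group-", maps[[1]]$mode), maps[[1]]$dims)
}

#' Dice coefficient between two label maps for one label
#'
#' `2 |A intersect B| / (|A| + |B|)` over the voxels carrying `label` in each
#' map; unassigned (NA) voxels are excluded. It is an error to ask for a
#' label absent from both maps.
#'
#' @param map_a,map_b `wta_map` objects on the same structure/geometry.
#' @param label cortical-system label 1..5.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(map_a, map_b, label) {
  if (!identical(map_a$voxels, map_b$voxels))
    stop("maps differ in structure or geometry")
  a <- !is.na(map_a$labels) & map_a$labels == label
  b <- !is.na(map_b$labels) & map_b$labels == label
  if (!any(a) && !any(b))
    stop("label ", label, " absent from both maps; Dice undefined")
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Dice profile between static and dynamic-mean maps
#'
#' Dice coefficient per (structure, label) between two maps, optionally
#' standardized by dividing each value by a reference profile (the healthy
#' control value for the same cell). Labels absent from both maps are
#' reported as absent (`NA`), not as 0.
#'
#' @param static,dynamic `wta_map` objects on the same structure.
#' @param reference optional data frame from a previous `dice_profile()`
#'   call (healthy-control reference); its `dice` column is the divisor.
#' @return data frame of class `dice_report`: `structure`, `label`,
#'   `system`, `dice`, and `standardized` when a reference is supplied.
#' @export
dice_profile <- function(static, dynamic, reference = NULL) {
  rows <- lapply(1:5, function(lab) {
    present <- any(static$labels == lab, na.rm = TRUE) ||
      any(dynamic$labels == lab, na.rm = TRUE)
    data.frame(structure = static$structure, label = lab,
               system = cortical_systems()[lab],
               dice = if (present) dice(static, dynamic, lab) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    ref <- reference$dice[match(out$label, reference$label)]
    if (any(!is.na(out$dice) & !is.na(ref) & ref == 0))
      stop("reference Dice of 0; standardization undefined")
    out$standardized <- out$dice / ref
  }
  class(out) <- c("dice_report", class(out))
  out
}
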