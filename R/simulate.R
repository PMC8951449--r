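#' Simulation configuration for synthetic BOLD cohorts
#'
#' Collects every knob of the synthetic-cohort generator. Defaults emulate
#' the acquisition and preprocessing regime the pipeline targets: TR 2 s,
#' 250 volumes per session, parcel signals band-limited to 0.01-0.08 Hz,
#' subcortical voxels coupled to their assigned cortical latent more strongly
#' than to the other four.
#'
#' @param grid_dims voxel grid, passed to [toy_atlas()].
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes volumes per session (before the initial discard).
#' @param n_per_group subjects per group label.
#' @param groups group labels; `HC` (healthy controls) plus two patient
#'   groups, generalized (`GE`) and focal (`FE`) epilepsy with
#'   tonic-clonic seizures.
#' @param band passband `(low_hz, high_hz)` of the latent signals.
#' @param alpha_win coupling of a subcortical voxel to its assigned cortical
#'   latent.
#' @param beta_cross coupling to each of the other four latents; must be
#'   smaller than `alpha_win` and non-negative, otherwise winner-take-all
#'   recovery is not identifiable.
#' @param noise_sd standard deviation of i.i.d. voxel noise.
#' @param regional_sd amplitude of the per-ROI regional fluctuation: every
#'   one of the 20 ROIs carries its own band-limited component shared by its
#'   voxels, emulating spontaneous regional activity not explained by the
#'   five cortical latents (and keeping the 20 ROI signals well-conditioned
#'   for full partial correlation).
#' @param global_sd amplitude of the shared global signal.
#' @param drift_sd across-scan linear drift amplitude (per-voxel SD).
#' @param motion_leak_sd SD of per-voxel weights coupling the pseudo-motion
#'   regressors into voxel series.
#' @param edge_effects data frame with columns `roi_i`, `roi_j`, `group`,
#'   `static_delta`, `dynamic_amplitude`: planted group-specific coupling
#'   effects between two ROIs (see [roi_names()] for valid ROI names).
#' @param duration_slopes data frame with columns `roi_i`, `roi_j`, `group`,
#'   `slope`: planted change of edge coupling per year of disease duration.
#' @param duration_lnorm named list of `meanlog`/`sdlog` pairs per patient
#'   group for the lognormal duration distribution. Defaults match mean 7.98
#'   (SD 8.32) years for GE and mean 9.42 (SD 6.56) years for FE.
#' @param dwell_tr mean dwell time (in TRs) of the two-state gain used for
#'   planted dynamic effects. The default of 100 TRs keeps dwells longer
#'   than the 50-TR analysis window, so most windows see a pure coupling
#'   state and the planted variability is expressible.
#' @param seed root seed; all cohort randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(24, 24, 16),
                       tr_seconds = 2,
                       n_volumes = 250,
                       n_per_group = 30,
                       groups = c("HC", "GE", "FE"),
                       band = c(0.01, 0.08),
                       alpha_win = 1.0,
                       beta_cross = 0.2,
                       noise_sd = 0.5,
                       regional_sd = 0.3,
                       global_sd = 0.3,
                       drift_sd = 0.2,
                       motion_leak_sd = 0.05,
                       edge_effects = empty_edge_effects(),
                       duration_slopes = empty_duration_slopes(),
                       duration_lnorm = list(
                         GE = lnorm_from_moments(7.98, 8.32),
                         FE = lnorm_from_moments(9.42, 6.56)
                       ),
                       dwell_tr = 100,
                       seed = 1L) {
  nyq <- 1 / (2 * tr_seconds)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop("band must satisfy 0 < low < high < Nyquist = ", nyq, " Hz")
  if (!(alpha_win > beta_cross && beta_cross >= 0))
    stop("need alpha_win > beta_cross >= 0 for identifiable WTA recovery")
  if (n_volumes <= 10) stop("n_volumes must exceed the initial discard of 10")
  stopifnot(n_per_group >= 1, length(groups) >= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> grid %s, TR %g s, %d volumes, %d/group (%s)\n",
    paste(x$grid_dims, collapse = "x"), x$tr_seconds, x$n_volumes,
    x$n_per_group, paste(x$groups, collapse = ", ")
  ))
  cat(sprintf("  band %g-%g Hz, alpha %g, beta %g, noise SD %g, seed %d\n",
              x$band[1], x$band[2], x$alpha_win, x$beta_cross, x$noise_sd,
              x$seed))
  cat(sprintf("  planted: %d edge effects, %d duration slopes\n",
              nrow(x$edge_effects), nrow(x$duration_slopes)))
  invisible(x)
}

#' @rdname sim_config
#' @export
empty_edge_effects <- function() {
  data.frame(roi_i = character(), roi_j = character(), group = character(),
             static_delta = numeric(), dynamic_amplitude = numeric())
}

#' @rdname sim_config
#' @export
empty_duration_slopes <- function() {
  data.frame(roi_i = character(), roi_j = character(), group = character(),
             slope = numeric())
}

#' Lognormal parameters matching a target mean and SD
#' @param m,s target mean and standard deviation on the natural scale.
#' @return list with `meanlog` and `sdlog`.
#' @export
lnorm_from_moments <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Band-limited Gaussian time series
#'
#' Draws a stationary Gaussian series whose spectral support lies inside
#' `[low_hz, high_hz]`: Fourier coefficients of the in-band frequency bins
#' are sampled as complex Gaussians, all out-of-band bins are zero, and the
#' inverse transform is standardized to zero mean, unit variance. By
#' construction, spectral power outside the band is zero.
#'
#' @param n_timepoints series length (>= 4).
#' @param tr_seconds sampling interval in seconds.
#' @param low_hz,high_hz passband edges; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr_seconds)`.
#' @param n_series number of independent series to draw.
#' @return numeric matrix `n_timepoints x n_series` (or a vector when
#'   `n_series = 1`), each column standardized.
#' @export
bandlimited_signal <- function(n_timepoints, tr_seconds, low_hz, high_hz,
                               n_series = 1L) {
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band (", low_hz, ", ", high_hz, ") Hz outside (0, Nyquist = ",
         nyq, " Hz)")
  n <- as.integer(n_timepoints)
  if (n < 4) stop("need at least 4 timepoints")
  freqs <- seq_len(n) - 1L
  freqs <- pmin(freqs, n - freqs) / (n * tr_seconds) # two-sided bin freqs
  keep_pos <- which(freqs >= low_hz & freqs <= high_hz &
                      (seq_len(n) - 1L) <= n %/% 2)
  if (length(keep_pos) == 0)
    stop("no frequency bin falls inside the band; series too short")
  out <- matrix(0, n, n_series)
  for (j in seq_len(n_series)) {
    spec <- complex(real = rep(0, n), imaginary = rep(0, n))
    coefs <- complex(real = stats::rnorm(length(keep_pos)),
                     imaginary = stats::rnorm(length(keep_pos)))
    spec[keep_pos] <- coefs
    # conjugate symmetry for a real-valued series
    mirror <- n - (keep_pos - 1L) + 1L
    ok <- mirror >= 1 & mirror <= n & mirror != keep_pos
    spec[mirror[ok]] <- Conj(coefs[ok])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    out[, j] <- (x - mean(x)) / stats::sd(x)
  }
  if (n_series == 1L) drop(out) else out
}

#' Two-state slow gain series
#'
#' Binary (0/1) gain with geometric dwell times, used to modulate planted
#' dynamic coupling so that sliding-window correlation alternates between a
#' coupled and an uncoupled state.
#'
#' @param n_timepoints series length.
#' @param dwell_tr mean dwell time in samples (geometric distribution).
#' @return numeric 0/1 vector of length `n_timepoints`.
#' @export
two_state_gain <- function(n_timepoints, dwell_tr = 40) {
  state <- stats::rbinom(1, 1, 0.5)
  g <- numeric(n_timepoints)
  t <- 1L
  while (t <= n_timepoints) {
    len <- 1L + stats::rgeom(1, 1 / dwell_tr)
    g[t:min(n_timepoints, t + len - 1L)] <- state
    t <- t + len
    state <- 1L - state
  }
  g
}

roi_voxels_from_truth <- function(roi, atlas, truth_labels) {
  # linear voxel indices of a named ROI, using planted ground-truth labels
  parts <- strsplit(roi, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed ROI name: ", roi)
  structure_name <- parts[1]
  lab <- match(parts[2], cortical_systems())
  if (is.na(lab)) stop("unknown cortical system in ROI name: ", roi)
  if (structure_name == "cortex") {
    which(atlas$cortex == lab)
  } else if (structure_name %in% subcortical_structures()) {
    which(truth_labels[[structure_name]] == lab)
  } else {
    stop("unknown structure in ROI name: ", roi)
  }
}

#' Generate one synthetic subject session
#'
#' Builds a 4D BOLD-like session from the latent-signal model: five
#' band-limited cortical latents s_1..s_5; each cortical voxel carries its
#' system's latent, each subcortical voxel with planted label L(v) carries
#' `alpha_win * s_L(v) + beta_cross * sum of the other four latents`; white
#' matter and CSF carry their own slow compartment signals; every voxel
#' receives a shared global component, a linear drift, a small pseudo-motion
#' leak, and i.i.d. Gaussian noise. Planted effects for the subject's group
#' add a shared band-limited source to both member ROIs of an edge: with
#' weight `static_delta` (constant), `dynamic_amplitude` (gated by a
#' two-state gain, [two_state_gain()]), and `slope * duration` for duration
#' slopes.
#'
#' @param config a [sim_config].
#' @param truth ground truth as returned by [generate_cohort()] (or a list
#'   with `voxel_labels` from [toy_atlas()]).
#' @param atlas an [atlas_bundle] on the configured grid.
#' @param record one-row phenotype data frame (`id`, `group`, `sex`, `age`,
#'   `duration_years`, `seizure_freq_per_month`).
#' @param subject_seed integer seed for this subject's randomness.
#' @return an object of class `subject_dataset`: list with `series`
#'   ([series4d]), `motion` (timepoints x 6 data frame, translations in mm
#'   and rotations in degrees) and `phenotype`.
#' @export
generate_subject <- function(config, truth, atlas, record, subject_seed) {
  if (!record$group %in% config$groups)
    stop("unknown group label: ", record$group)
  set.seed(as.integer(subject_seed))
  nt <- config$n_volumes
  dims <- config$grid_dims
  nv <- prod(dims)
  tr <- config$tr_seconds

  lat <- bandlimited_signal(nt, tr, config$band[1], config$band[2],
                            n_series = 5L)
  lat_sum <- rowSums(lat)
  global <- bandlimited_signal(nt, tr, config$band[1], config$band[2])
  wm_sig <- bandlimited_signal(nt, tr, config$band[1], config$band[2])
  csf_sig <- bandlimited_signal(nt, tr, config$band[1], config$band[2])

  # motion: slow random walks, translations (mm) and rotations (deg)
  motion <- vapply(1:6, function(j) cumsum(stats::rnorm(nt, 0, 0.02)),
                   numeric(nt))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

  x <- matrix(stats::rnorm(nt * nv, 0, config$noise_sd), nt, nv)

  # cortical voxels: system latent
  for (lab in 1:5) {
    vox <- which(atlas$cortex == lab)
    x[, vox] <- x[, vox] + lat[, lab]
  }
  # subcortical voxels: winner latent + cross-talk
  for (s in subcortical_structures()) {
    tl <- truth$voxel_labels[[s]]
    for (lab in 1:5) {
      vox <- which(tl == lab)
      if (!length(vox)) next
      sig <- config$alpha_win * lat[, lab] +
        config$beta_cross * (lat_sum - lat[, lab])
      x[, vox] <- x[, vox] + sig
    }
  }
  # per-ROI regional fluctuations (shared within each of the 20 ROIs)
  if (config$regional_sd > 0) {
    reg <- bandlimited_signal(nt, tr, config$band[1], config$band[2],
                              n_series = 20L)
    for (k in seq_along(roi_names())) {
      vox <- roi_voxels_from_truth(roi_names()[k], atlas, truth$voxel_labels)
      x[, vox] <- x[, vox] + config$regional_sd * reg[, k]
    }
  }
  # nuisance compartments
  x[, atlas$wm] <- x[, atlas$wm] + wm_sig
  x[, atlas$csf] <- x[, atlas$csf] + csf_sig

  # planted edge effects for this subject's group
  eff <- config$edge_effects
  eff <- eff[eff$group == record$group, , drop = FALSE]
  if (nrow(eff)) {
    for (k in seq_len(nrow(eff))) {
      vi <- roi_voxels_from_truth(eff$roi_i[k], atlas, truth$voxel_labels)
      vj <- roi_voxels_from_truth(eff$roi_j[k], atlas, truth$voxel_labels)
      w <- eff$static_delta[k]
      if (!is.na(w) && w != 0) {
        e <- bandlimited_signal(nt, tr, config$band[1], config$band[2])
        x[, vi] <- x[, vi] + sqrt(abs(w)) * e
        x[, vj] <- x[, vj] + sign(w) * sqrt(abs(w)) * e
      }
      a <- eff$dynamic_amplitude[k]
      if (!is.na(a) && a != 0) {
        e <- bandlimited_signal(nt, tr, config$band[1], config$band[2])
        g <- two_state_gain(nt, config$dwell_tr)
        ge <- sqrt(a) * g * e
        x[, vi] <- x[, vi] + ge
        x[, vj] <- x[, vj] + ge
      }
    }
  }
  # duration-dependent coupling
  slopes <- config$duration_slopes
  slopes <- slopes[slopes$group == record$group, , drop = FALSE]
  if (nrow(slopes) && !is.na(record$duration_years)) {
    for (k in seq_len(nrow(slopes))) {
      w <- slopes$slope[k] * record$duration_years
      if (w == 0) next
      vi <- roi_voxels_from_truth(slopes$roi_i[k], atlas, truth$voxel_labels)
      vj <- roi_voxels_from_truth(slopes$roi_j[k], atlas, truth$voxel_labels)
      e <- bandlimited_signal(nt, tr, config$band[1], config$band[2])
      x[, vi] <- x[, vi] + sqrt(abs(w)) * e
      x[, vj] <- x[, vj] + sign(w) * sqrt(abs(w)) * e
    }
  }

  # shared global component, per-voxel linear drift, pseudo-motion leak
  x <- x + config$global_sd * global
  tt <- seq(0, 1, length.out = nt)
  drift_slopes <- stats::rnorm(nv, 0, config$drift_sd)
  x <- x + outer(tt - mean(tt), drift_slopes)
  leak <- motion %*% matrix(stats::rnorm(6 * nv, 0, config$motion_leak_sd),
                            6, nv)
  x <- x + leak

  series <- series4d(array(t(x), dim = c(dims, nt)), tr)
  structure(list(series = series,
                 motion = as.data.frame(motion),
                 phenotype = record),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s (group %s): ", x$phenotype$id,
              x$phenotype$group))
  print(x$series)
  invisible(x)
}

#' Generate the phenotype table of a synthetic cohort
#'
#' Sex counts are matched across groups by construction (male fraction
#' 75/114); ages are drawn from the same normal distribution (mean 26,
#' SD 7.5, truncated to 18-55 years) in every group; durations for the
#' patient groups follow the configured lognormal distributions; HC
#' durations and seizure frequencies are missing.
#'
#' @param config a [sim_config].
#' @return data frame with one row per subject: `id`, `group`, `sex`,
#'   `age`, `duration_years`, `seizure_freq_per_month`, `subject_seed`.
#' @export
generate_phenotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_per_group
  n_male <- round(n * 75 / 114)
  rows <- lapply(config$groups, function(g) {
    age <- stats::rnorm(n, 26, 7.5)
    age <- pmin(pmax(age, 18), 55)
    dur <- rep(NA_real_, n)
    freq <- rep(NA_real_, n)
    if (g %in% names(config$duration_lnorm)) {
      p <- config$duration_lnorm[[g]]
      dur <- stats::rlnorm(n, p$meanlog, p$sdlog)
      freq <- stats::rlnorm(n, log(2.2) - 0.5, 1)
    }
    data.frame(
      id = sprintf("%s%03d", g, seq_len(n)),
      group = g,
      sex = rep(c("M", "F"), c(n_male, n - n_male)),
      age = age,
      duration_years = dur,
      seizure_freq_per_month = freq
    )
  })
  ph <- do.call(rbind, rows)
  ph$subject_seed <- sample.int(.Machine$integer.max - 1L, nrow(ph))
  rownames(ph) <- NULL
  ph
}

#' Generate a full synthetic cohort with ground truth
#'
#' @param config a [sim_config].
#' @param materialize if `TRUE` (default) every subject's 4D session is
#'   generated and returned; if `FALSE` only phenotypes, atlas and ground
#'   truth are returned and sessions are produced on demand with
#'   [generate_subject()] (memory-light streaming for large cohorts).
#' @return list of class `synthetic_cohort`: `subjects` (list of
#'   [generate_subject()] outputs, or `NULL`), `truth` (class
#'   `ground_truth`: planted voxel labels, edge effects, duration slopes and
#'   the subject table), `atlas`, `phenotypes`, `config`.
#' @export
generate_cohort <- function(config, materialize = TRUE) {
  ta <- toy_atlas(config$grid_dims)
  ph <- generate_phenotypes(config)
  truth <- structure(list(voxel_labels = ta$truth_labels,
                          edge_effects = config$edge_effects,
                          duration_slopes = config$duration_slopes,
                          subject_table = ph),
                     class = "ground_truth")
  subjects <- NULL
  if (materialize) {
    subjects <- lapply(seq_len(nrow(ph)), function(i) {
      generate_subject(config, truth, ta$atlas, ph[i, , drop = FALSE],
                       ph$subject_seed[i])
    })
    names(subjects) <- ph$id
  }
  structure(list(subjects = subjects, truth = truth, atlas = ta$atlas,
                 phenotypes = ph, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s)%s\n",
              nrow(x$phenotypes),
              paste(table(x$phenotypes$group)[unique(x$phenotypes$group)],
                    collapse = "/"),
              if (is.null(x$subjects)) " [not materialized]" else ""))
  invisible(x)
}

#' Matrix-level cohort simulator for statistical-power studies
#'
#' Draws per-subject 20x20 Fisher-z connectivity matrices directly from the
#' edge-effect model, bypassing voxel-level generation: every unique edge has
#' a baseline z shared across subjects, group effects add `delta`, duration
#' slopes add `slope * duration`, and subject noise is i.i.d. Gaussian. The
#' default `noise_sd` of 0.1 reflects the sampling error of a Fisher-z
#' estimate from 240 timepoints plus between-subject variability. Used for
#' replicated validity checks (null FDR calibration, power, interaction
#' recovery) where repeated voxel-level cohorts would be needlessly slow.
#'
#' @param n_per_group named integer vector, subjects per group.
#' @param effects data frame `roi_i`, `roi_j`, `group`, `delta` (additive
#'   z-shift for that group) or `NULL`.
#' @param duration_slopes data frame `roi_i`, `roi_j`, `group`, `slope` or
#'   `NULL`.
#' @param duration_lnorm as in [sim_config()]; used for groups named there.
#' @param noise_sd per-edge subject noise SD (z units).
#' @param kind connectivity kind tag of the generated matrices.
#' @param seed integer seed.
#' @return list: `matrices` (list of [connectivity_matrix]), `group`
#'   (character vector), `duration_years` (numeric vector).
#' @export
simulate_edge_cohort <- function(n_per_group,
                                 effects = NULL,
                                 duration_slopes = NULL,
                                 duration_lnorm = list(
                                   GE = lnorm_from_moments(7.98, 8.32),
                                   FE = lnorm_from_moments(9.42, 6.56)
                                 ),
                                 noise_sd = 0.1,
                                 kind = "static_z",
                                 seed = 1L) {
  set.seed(as.integer(seed))
  stopifnot(!is.null(names(n_per_group)))
  rn <- roi_names()
  base <- matrix(0, 20, 20, dimnames = list(rn, rn))
  ut <- upper.tri(base)
  base[ut] <- stats::rnorm(sum(ut), 0.2, 0.1)
  base <- base + t(base)

  group <- rep(names(n_per_group), n_per_group)
  dur <- rep(NA_real_, length(group))
  for (g in intersect(names(duration_lnorm), names(n_per_group))) {
    idx <- which(group == g)
    p <- duration_lnorm[[g]]
    dur[idx] <- stats::rlnorm(length(idx), p$meanlog, p$sdlog)
  }

  shift_for <- function(tab, g, d) {
    m <- matrix(0, 20, 20, dimnames = list(rn, rn))
    if (is.null(tab)) return(m)
    rows <- tab[tab$group == g, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      i <- match(rows$roi_i[k], rn); j <- match(rows$roi_j[k], rn)
      if (is.na(i) || is.na(j)) stop("unknown ROI in effects table")
      val <- if (!is.null(rows$delta)) rows$delta[k] else rows$slope[k] * d
      m[i, j] <- m[i, j] + val
      m[j, i] <- m[j, i] + val
    }
    m
  }

  mats <- lapply(seq_along(group), function(s) {
    noise <- matrix(0, 20, 20)
    noise[ut] <- stats::rnorm(sum(ut), 0, noise_sd)
    noise <- noise + t(noise)
    m <- base + shift_for(effects, group[s], NA) +
      shift_for(duration_slopes, group[s],
                if (is.na(dur[s])) 0 else dur[s]) + noise
    diag(m) <- 0
    new_connectivity_matrix(m, kind)
  })
  list(matrices = mats, group = group, duration_years = dur)
}

#' Write a subject dataset and atlas to disk
#'
#' Serializes a synthetic subject in standard interchange formats: 4D series
#' and atlas volumes as NIfTI-1, motion parameters and phenotype as TSV,
#' planted ground-truth labels as JSON.
#'
#' @param dataset a `subject_dataset` from [generate_subject()].
#' @param atlas an [atlas_bundle].
#' @param truth optional `ground_truth` (planted labels go to JSON).
#' @param directory output directory (created if missing).
#' @return invisibly, a named character vector manifest of written paths.
#' @export
write_dataset <- function(dataset, atlas, directory, truth = NULL) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", directory)
  id <- dataset$phenotype$id
  paths <- c()
  f <- file.path(directory, paste0(id, "_bold.nii.gz"))
  img <- RNifti::asNifti(dataset$series$data)
  RNifti::pixdim(img) <- c(rep(dataset$series$voxel_mm, 3),
                           dataset$series$tr_seconds)
  RNifti::writeNifti(img, f)
  paths["bold"] <- f

  f <- file.path(directory, "atlas_cortex.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas$cortex, datatype = "int16"), f)
  paths["atlas_cortex"] <- f
  for (nm in c(subcortical_structures(), "wm", "csf")) {
    f <- file.path(directory, paste0("atlas_", nm, ".nii.gz"))
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(atlas[[nm]]), dim = atlas$dims),
                      datatype = "int16"), f)
    paths[paste0("atlas_", nm)] <- f
  }

  f <- file.path(directory, paste0(id, "_motion.tsv"))
  utils::write.table(dataset$motion, f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths["motion"] <- f
  f <- file.path(directory, paste0(id, "_phenotype.tsv"))
  utils::write.table(dataset$phenotype, f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths["phenotype"] <- f

  meta <- list(id = id, tr_seconds = dataset$series$tr_seconds,
               grid_dims = dim(dataset$series$data)[1:3])
  if (!is.null(truth)) {
    meta$voxel_labels <- lapply(truth$voxel_labels, as.vector)
    meta$edge_effects <- truth$edge_effects
    meta$duration_slopes <- truth$duration_slopes
  }
  f <- file.path(directory, paste0(id, "_truth.json"))
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- f
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory directory written by [write_dataset()].
#' @param id subject identifier.
#' @return list with `series` ([series4d]), `motion`, `phenotype`, `atlas`
#'   ([atlas_bundle]).
#' @export
read_dataset <- function(directory, id) {
  meta <- jsonlite::read_json(file.path(directory, paste0(id, "_truth.json")),
                              simplifyVector = TRUE)
  img <- RNifti::readNifti(file.path(directory, paste0(id, "_bold.nii.gz")))
  series <- series4d(array(as.numeric(img), dim = dim(img)),
                     tr_seconds = meta$tr_seconds)
  motion <- utils::read.delim(file.path(directory, paste0(id, "_motion.tsv")))
  phenotype <- utils::read.delim(
    file.path(directory, paste0(id, "_phenotype.tsv")))
  rd <- function(nm) {
    a <- RNifti::readNifti(file.path(directory, paste0("atlas_", nm, ".nii.gz")))
    array(as.integer(a), dim = dim(a))
  }
  atlas <- atlas_bundle(rd("cortex"),
                        rd("striatum") > 0, rd("thalamus") > 0,
                        rd("cerebellum") > 0, rd("wm") > 0, rd("csf") > 0)
  list(series = series, motion = motion, phenotype = phenotype, atlas = atlas)
}
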