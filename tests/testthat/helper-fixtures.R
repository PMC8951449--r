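# Shared fixtures: a small, fast cohort geometry used across unit tests.
# The full-scale (24x24x16, 250-volume) conditions are exercised in
# test-acceptance.R only.

small_config <- function(..., seed = 42L) {
  # 130 volumes: after the 10-volume discard, the 0.01-0.08 Hz band spans
  # 17 Fourier bins (34 real dof), enough for 20-ROI partial correlation
  sim_config(grid_dims = c(12, 12, 10), n_volumes = 130, n_per_group = 4,
             seed = seed, ...)
}

# lazily-built processed small cohort shared by several test files
.fixture_env <- new.env(parent = emptyenv())

small_processed_cohort <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  ph <- coh$phenotypes
  structures <- subcortical_structures()
  maps <- list(); sigs <- list()
  for (i in seq_len(nrow(ph))) {
    pp <- preprocess_subject(coh$subjects[[i]], coh$atlas)
    psig <- parcel_mean_signals(pp$series, coh$atlas)
    maps[[ph$id[i]]] <- lapply(setNames(structures, structures), function(s)
      voxel_partial_wta(pp$series, coh$atlas[[s]], psig, s))
    sigs[[ph$id[i]]] <- pp
  }
  hc_ids <- ph$id[ph$group == "HC"]
  hc_maps <- lapply(setNames(structures, structures), function(s)
    group_wta(lapply(maps[hc_ids], `[[`, s)))
  rois <- define_rois(hc_maps, coh$atlas)
  roi_sigs <- lapply(sigs, function(pp) roi_mean_signals(pp$series, rois))
  .fixture_env$small <- list(cfg = cfg, cohort = coh, maps = maps,
                             hc_maps = hc_maps, rois = rois,
                             preprocessed = sigs, roi_signals = roi_sigs)
  .fixture_env$small
}

# deterministic fabricated wta_map for label-geometry tests
fake_wta_map <- function(labels, structure = "striatum", mode = "static") {
  n <- length(labels)
  coefs <- matrix(0, n, 5)
  ok <- !is.na(labels)
  coefs[cbind(which(ok), labels[ok])] <- 1
  coefs[!ok, ] <- NA_real_
  cstcnet:::new_wta_map(structure, seq_len(n), labels, coefs, mode,
                        c(n, 1, 1))
}

# symmetric z-matrix with zero diagonal from a seed
random_cm <- function(seed, kind = "static_z", base = 0) {
  set.seed(seed)
  m <- matrix(0, 20, 20)
  m[upper.tri(m)] <- rnorm(190, base, 0.2)
  m <- m + t(m)
  cstcnet:::new_connectivity_matrix(m, kind)
}
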