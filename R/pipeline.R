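#' Process one subject through preprocessing and network construction
#'
#' Convenience wrapper: preprocess, extract ROI signals, and build the
#' static z and dynamic-variability matrices.
#'
#' @param dataset a `subject_dataset`.
#' @param atlas an [atlas_bundle].
#' @param rois a [define_rois()] ROI set.
#' @param n_discard,band,window_tr,step_tr stage parameters.
#' @return list `roi_signals`, `static` (`connectivity_matrix`), `dfc_sd`
#'   (`connectivity_matrix`), `kept`; `NULL` matrices when the subject is
#'   motion-excluded.
#' @export
process_subject <- function(dataset, atlas, rois, n_discard = 10L,
                            band = c(0.01, 0.08), window_tr = 50L,
                            step_tr = 5L) {
  pp <- preprocess_subject(dataset, atlas, n_discard, band)
  if (!pp$kept)
    return(list(roi_signals = NULL, static = NULL, dfc_sd = NULL,
                kept = FALSE))
  sig <- roi_mean_signals(pp$series, rois)
  list(roi_signals = sig,
       static = static_network(sig),
       dfc_sd = dfc_variability(dynamic_network(sig, window_tr, step_tr)),
       kept = TRUE)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(roi = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage: cohort generation, preprocessing,
#' winner-take-all parcellation (subject and group level, static and
#' dynamic), ROI definition from the healthy-control static maps, network
#' construction, edgewise group statistics, duration models, classification
#' of the two patient groups, and reproducibility analyses. Writes
#' intermediate artifacts with content hashes to `workdir`; a rerun with the
#' same configuration and seed reproduces identical hashes.
#'
#' @param config a [sim_config]; its `seed` drives all randomness.
#' @param workdir output directory for artifacts.
#' @param n_discard,band,window_tr,step_tr,n_folds,q_threshold stage
#'   parameters (defaults: discard 10, band 0.01-0.08 Hz, window 50 TRs,
#'   step 5 TRs, 10 folds, q < 0.05).
#' @param classify run the SVM classification stage (default TRUE).
#' @return object of class `pipeline_result`: kept phenotypes, group WTA
#'   maps, Dice reports, per-group matrix lists, edgewise statistics,
#'   classification results, reproducibility reports, and the artifact
#'   `manifest` (paths + md5 hashes).
#' @export
run_pipeline <- function(config, workdir, n_discard = 10L,
                         band = config$band, window_tr = 50L, step_tr = 5L,
                         n_folds = 10L, q_threshold = 0.05,
                         classify = TRUE) {
  ok <- dir.exists(workdir) || dir.create(workdir, recursive = TRUE)
  if (!ok) stop("cannot create workdir: ", workdir)
  wtag <- paste0("w", window_tr)
  cohort <- generate_cohort(config, materialize = FALSE)
  atlas <- cohort$atlas
  ph <- cohort$phenotypes

  regen <- function(i) generate_subject(config, cohort$truth, atlas,
                                        ph[i, , drop = FALSE],
                                        ph$subject_seed[i])

  # stage 1: preprocessing + subject WTA maps, group maps per group
  structures <- subcortical_structures()
  subj_maps <- list()
  kept <- logical(nrow(ph))
  for (i in seq_len(nrow(ph))) {
    ds <- regen(i)
    pp <- preprocess_subject(ds, atlas, n_discard, band)
    kept[i] <- pp$kept
    if (!pp$kept) next
    sig <- parcel_mean_signals(pp$series, atlas)
    subj_maps[[ph$id[i]]] <- lapply(stats::setNames(structures, structures),
      function(s) list(
        static = voxel_partial_wta(pp$series, atlas[[s]], sig, s),
        dynamic = windowed_voxel_wta(pp$series, atlas[[s]], sig,
                                     window_tr, step_tr, s)))
  }
  if (!any(kept[ph$group == config$groups[1]]))
    stop("pipeline halted at parcellation: no usable subjects in group ",
         config$groups[1])

  group_maps <- lapply(stats::setNames(config$groups, config$groups),
    function(g) {
      ids <- ph$id[ph$group == g & kept]
      lapply(stats::setNames(structures, structures), function(s) list(
        static = group_wta(lapply(subj_maps[ids], function(m) m[[s]]$static)),
        dynamic = group_wta(lapply(subj_maps[ids], function(m) m[[s]]$dynamic))
      ))
    })

  # Dice: static vs dynamic-mean per group, standardized by the HC profile
  hc <- config$groups[1]
  dice_reports <- lapply(stats::setNames(config$groups, config$groups),
    function(g) {
      do.call(rbind, lapply(structures, function(s) {
        ref <- if (g == hc) NULL
          else dice_profile(group_maps[[hc]][[s]]$static,
                            group_maps[[hc]][[s]]$dynamic)
        dice_profile(group_maps[[g]][[s]]$static,
                     group_maps[[g]][[s]]$dynamic, ref)
      }))
    })

  # stage 2: ROI set from HC static maps, per-subject networks
  rois <- define_rois(lapply(stats::setNames(structures, structures),
                             function(s) group_maps[[hc]][[s]]$static), atlas)
  roi_signals <- list(); static_m <- list(); dfc_m <- list()
  for (i in which(kept)) {
    ds <- regen(i)
    res <- process_subject(ds, atlas, rois, n_discard, band, window_tr,
                           step_tr)
    roi_signals[[ph$id[i]]] <- res$roi_signals
    static_m[[ph$id[i]]] <- res$static
    dfc_m[[ph$id[i]]] <- res$dfc_sd
  }
  ph_kept <- ph[kept, , drop = FALSE]

  by_group <- function(lst, g) lst[ph_kept$id[ph_kept$group == g]]
  groups <- config$groups
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  edgewise <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    edgewise[[paste0(key, ".static")]] <-
      edgewise_ttest(by_group(static_m, pr[1]), by_group(static_m, pr[2]),
                     q_threshold)
    edgewise[[paste0(key, ".dfc_sd.", wtag)]] <-
      edgewise_ttest(by_group(dfc_m, pr[1]), by_group(dfc_m, pr[2]),
                     q_threshold)
  }

  patients <- setdiff(groups, hc)
  duration_stats <- list()
  for (g in patients) {
    sel <- ph_kept$group == g
    if (sum(sel) >= 4 && stats::sd(ph_kept$duration_years[sel]) > 0)
      duration_stats[[g]] <- edgewise_duration_correlation(
        by_group(static_m, g), ph_kept$duration_years[sel], q_threshold)
  }
  interaction_stats <- NULL
  if (length(patients) == 2) {
    sel <- ph_kept$group %in% patients
    interaction_stats <- interaction_model(
      static_m[ph_kept$id[sel]], ph_kept$group[sel],
      ph_kept$duration_years[sel], q_threshold)
  }
  balance <- cohort_balance(ph_kept)

  # stage 3: classification of the two patient groups
  classification <- NULL
  if (classify && length(patients) == 2) {
    sel <- ph_kept$group %in% patients
    labels <- ifelse(ph_kept$group[sel] == patients[1], 1L, -1L)
    ids <- ph_kept$id[sel]
    classification <- lapply(
      stats::setNames(c("static", "dynamic", "combined"),
                      c("static", "dynamic", "combined")),
      function(fs) crossvalidated_svm(
        feature_table(static_m[ids], dfc_m[ids], labels, fs),
        n_folds = n_folds, seed = config$seed))
  }

  # stage 4: reproducibility
  split <- split_half(ph_kept, seed = config$seed)
  split_cors <- lapply(stats::setNames(groups, groups), function(g) {
    rows <- which(ph_kept$group == g)
    h1 <- ph_kept$id[rows[split$assignment[rows] == 1L]]
    h2 <- ph_kept$id[rows[split$assignment[rows] == 2L]]
    if (length(h1) < 2 || length(h2) < 2) return(NULL)
    list(static = pattern_correlation(group_mean_matrix(static_m[h1]),
                                      group_mean_matrix(static_m[h2])),
         dfc_sd = pattern_correlation(group_mean_matrix(dfc_m[h1]),
                                      group_mean_matrix(dfc_m[h2])))
  })
  nt_pp <- nrow(roi_signals[[1]])
  sweep_sizes <- c(30, 60, 100)
  sweep_sizes <- sweep_sizes[sweep_sizes <= nt_pp]
  sweep <- NULL
  if (length(sweep_sizes) && window_tr <= nt_pp)
    sweep <- window_sweep(roi_signals, sweep_sizes, step_tr, window_tr)

  # artifacts
  paths <- c()
  for (g in groups) {
    f <- file.path(workdir, paste0("mean_static_", g, ".tsv"))
    write_matrix_tsv(group_mean_matrix(by_group(static_m, g)), f)
    paths <- c(paths, f)
    f <- file.path(workdir, paste0("mean_dfc_sd_", wtag, "_", g, ".tsv"))
    write_matrix_tsv(group_mean_matrix(by_group(dfc_m, g)), f)
    paths <- c(paths, f)
    f <- file.path(workdir, paste0("dice_", g, ".tsv"))
    utils::write.table(dice_reports[[g]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, f)
  }
  for (nm in names(edgewise)) {
    f <- file.path(workdir, paste0("edgewise_", nm, ".tsv"))
    utils::write.table(edgewise[[nm]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, f)
  }
  f <- file.path(workdir, "phenotypes.tsv")
  utils::write.table(ph_kept, f, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)
  if (!is.null(classification)) {
    f <- file.path(workdir, "classification.json")
    jsonlite::write_json(lapply(classification, function(cr) cr$pooled), f,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, f)
  }
  manifest <- data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  params <- list(n_discard = n_discard, band = band, window_tr = window_tr,
                 step_tr = step_tr, n_folds = n_folds,
                 q_threshold = q_threshold, seed = config$seed)
  jsonlite::write_json(list(params = params, files = manifest),
                       file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(phenotypes = ph_kept, kept = kept,
                 group_maps = group_maps, dice = dice_reports, rois = rois,
                 roi_signals = roi_signals,
                 static_matrices = static_m, dfc_matrices = dfc_m,
                 edgewise = edgewise, duration = duration_stats,
                 interaction = interaction_stats, balance = balance,
                 classification = classification, split = split,
                 split_correlations = split_cors, window_sweep = sweep,
                 manifest = manifest, params = params),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects kept (%s)\n",
              nrow(x$phenotypes),
              paste(names(table(x$phenotypes$group)), collapse = "/")))
  n_sig <- vapply(x$edgewise, function(e) sum(e$significant), integer(1))
  cat("  significant edges per contrast:\n")
  for (nm in names(n_sig)) cat(sprintf("    %-28s %d\n", nm, n_sig[nm]))
  if (!is.null(x$classification)) {
    for (nm in names(x$classification))
      cat(sprintf("  %s accuracy: %.2f%%\n", nm,
                  100 * x$classification[[nm]]$pooled$accuracy))
  }
  invisible(x)
}
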