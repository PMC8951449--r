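#' Names of the five cortical systems
#'
#' The fixed partition of the cortex used throughout: prefrontal,
#' motor/premotor, somatosensory, parietal/occipital and temporal cortex,
#' coded 1 to 5 in atlas label volumes.
#'
#' @return character vector of length 5.
#' @export
cortical_systems <- function() {
  c("prefrontal", "motor", "somatosensory", "parietooccipital", "temporal")
}

#' Names of the subcortical structures that are parcellated
#' @return character vector of length 3.
#' @export
subcortical_structures <- function() c("striatum", "thalamus", "cerebellum")

#' Atlas bundle: cortical labels, structure masks and nuisance compartments
#'
#' @param cortex integer 3D array; 0 outside the cortex, 1..5 for the five
#'   cortical systems (see [cortical_systems()]).
#' @param striatum,thalamus,cerebellum logical 3D masks of the three
#'   subcortical structures.
#' @param wm,csf logical 3D masks of white matter and cerebrospinal fluid
#'   used for nuisance regression.
#' @return an object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(cortex, striatum, thalamus, cerebellum, wm, csf) {
  vols <- list(striatum = striatum, thalamus = thalamus,
               cerebellum = cerebellum, wm = wm, csf = csf)
  d <- dim(cortex)
  if (length(d) != 3L) stop("`cortex` must be a 3D label array")
  for (nm in names(vols)) {
    v <- vols[[nm]]
    if (!identical(dim(v), d)) stop("mask `", nm, "` does not match the cortex grid")
    if (!any(v)) stop("mask `", nm, "` is empty")
  }
  if (!any(cortex > 0)) stop("cortex label volume is empty")
  if (!all(cortex %in% 0:5)) stop("cortex labels must be integers 0..5")
  for (lab in 1:5) {
    if (!any(cortex == lab))
      stop("cortical system ", lab, " (", cortical_systems()[lab], ") is empty")
  }
  # label sets must be disjoint
  occ <- (cortex > 0) + Reduce(`+`, vols)
  if (any(occ > 1)) stop("atlas volumes overlap; label sets must be disjoint")
  structure(c(list(cortex = cortex), vols, list(dims = d)),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> grid %s\n", paste(x$dims, collapse = "x")))
  cat(sprintf("  cortex: %d voxels in 5 systems\n", sum(x$cortex > 0)))
  for (s in subcortical_structures())
    cat(sprintf("  %s: %d voxels\n", s, sum(x[[s]])))
  cat(sprintf("  WM: %d, CSF: %d voxels\n", sum(x$wm), sum(x$csf)))
  invisible(x)
}

split_indices <- function(n, k) {
  # contiguous near-equal chunks of 1:n
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  split(seq_len(n), rep(seq_len(k), sizes))
}

#' Block-shaped toy atlas on a small voxel grid
#'
#' Builds a simple laminar geometry used by the synthetic cohort generator:
#' a CSF slab at the bottom of the grid, the three subcortical structures as
#' adjacent blocks above it (striatum, thalamus, cerebellum along y), a white
#' matter slab, and the cortex as the top slices partitioned into five
#' x-strips, one per cortical system. Each subcortical structure is divided
#' into the same five x-strips; these strips are the planted ground-truth
#' affiliation of its voxels to the cortical systems.
#'
#' @param grid_dims integer vector of 3 grid dimensions; minimum 10x9x10.
#' @return list with elements `atlas` (an [atlas_bundle]) and `truth_labels`
#'   (per structure, an integer 3D array with planted labels 1..5, 0 outside
#'   the structure).
#' @export
toy_atlas <- function(grid_dims = c(24, 24, 16)) {
  stopifnot(length(grid_dims) == 3)
  nx <- grid_dims[1]; ny <- grid_dims[2]; nz <- grid_dims[3]
  if (nx < 10 || ny < 9 || nz < 10)
    stop("grid too small for the laminar toy geometry (need >= 10x9x10)")
  z_csf <- seq_len(max(1L, floor(0.12 * nz)))
  sub_lo <- max(z_csf) + 2L
  sub_hi <- sub_lo + max(2L, floor(0.28 * nz)) - 1L
  wm_lo <- sub_hi + 2L
  wm_hi <- wm_lo + max(1L, floor(0.1 * nz)) - 1L
  ctx_lo <- wm_hi + 2L
  if (ctx_lo > nz - 1L) stop("grid too shallow to fit cortex slices")
  zero <- array(0L, grid_dims)
  fal <- array(FALSE, grid_dims)

  xs <- split_indices(nx, 5)
  ys <- split_indices(ny, 3)

  cortex <- zero
  for (lab in 1:5) cortex[xs[[lab]], , ctx_lo:nz] <- lab

  structs <- list(striatum = fal, thalamus = fal, cerebellum = fal)
  truth <- list(striatum = zero, thalamus = zero, cerebellum = zero)
  for (k in 1:3) {
    nm <- subcortical_structures()[k]
    m <- fal
    m[, ys[[k]], sub_lo:sub_hi] <- TRUE
    structs[[nm]] <- m
    tl <- zero
    for (lab in 1:5) tl[xs[[lab]], ys[[k]], sub_lo:sub_hi] <- lab
    truth[[nm]] <- tl
  }

  wm <- fal; wm[, , wm_lo:wm_hi] <- TRUE
  csf <- fal; csf[, , z_csf] <- TRUE

  atlas <- atlas_bundle(cortex, structs$striatum, structs$thalamus,
                        structs$cerebellum, wm, csf)
  list(atlas = atlas, truth_labels = truth)
}
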