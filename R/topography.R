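#' Planted-topography specification
#'
#' Parameters of the ground-truth connectivity topography planted in
#' synthetic cohorts.  Entorhinal voxels mix the PRC and PHC latent
#' signals with a PHC weight `w` that follows a logistic ramp along a
#' spatial gradient; subicular voxels mix anterior-lateral-EC-like and
#' posterior-medial-EC-like signals along each slice's transverse
#' (proximo-distal) axis, with extra direct seed coupling at the
#' longitudinal ends of the subiculum.
#'
#' @param gradient_direction Length-3 vector in index space along which the
#'   PHC weight increases.  The default points anterior-lateral to
#'   posterior-medial: x increasing (lateral to medial) and y decreasing
#'   (anterior to posterior).
#' @param mixing_steepness Logistic slope per voxel of projected distance.
#'   0 gives a flat `w = 0.5` everywhere.
#' @param sub_transverse_steepness Logistic slope per transverse voxel for
#'   the subiculum proximo-distal gradient.
#' @param end_coupling Amplitude (in latent-signal SD units) of the direct
#'   PRC coupling added to the most anterior `end_slices` subiculum slices
#'   and of the direct PHC coupling added to the most posterior ones.
#' @param end_slices Number of coupled slices at each longitudinal end
#'   (default 8).
#' @param direct_pathway_weight Fraction of each neocortical seed's signal
#'   carried by a private component that reaches the subiculum ends
#'   directly but is not relayed through the EC (see the methods vignette).
#' @return An object of class `topography_spec`.
#' @export
topography_spec <- function(gradient_direction = c(1, -1, 0),
                            mixing_steepness = 0.3,
                            sub_transverse_steepness = 0.8,
                            end_coupling = 0.8,
                            end_slices = 8L,
                            direct_pathway_weight = 0.6) {
  if (length(gradient_direction) != 3L || !is.numeric(gradient_direction))
    stop("gradient_direction must be a length-3 numeric vector", call. = FALSE)
  nrm <- sqrt(sum(gradient_direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("gradient_direction must be a nonzero vector", call. = FALSE)
  if (mixing_steepness < 0 || sub_transverse_steepness < 0)
    stop("steepness parameters must be nonnegative", call. = FALSE)
  if (end_coupling < 0) stop("end_coupling must be nonnegative", call. = FALSE)
  structure(list(gradient_direction = gradient_direction / nrm,
                 mixing_steepness = mixing_steepness,
                 sub_transverse_steepness = sub_transverse_steepness,
                 end_coupling = end_coupling,
                 end_slices = as.integer(end_slices),
                 direct_pathway_weight = direct_pathway_weight),
            class = "topography_spec")
}

#' Plant the ground-truth connectivity topography on an atlas
#'
#' Computes, for every EC voxel, the PHC-signal mixing weight
#' `w(v) = logistic(steepness * <v - centroid, g>)` and the implied
#' ground-truth label (PHC-preferring where `w > 0.5`, PRC-preferring
#' otherwise, with the tie `w = 0.5` going to PRC), and for every
#' subiculum voxel the transverse (proximo-distal) mixing weight plus the
#' end-slice membership used for direct seed coupling.
#'
#' @param atlas A `labeled_atlas` with EC and SUB regions.
#' @param topo A [topography_spec()].
#' @return An object of class `ground_truth` with data frames `ec`
#'   (voxel, coordinates, `weight`, `label`) and `sub` (voxel,
#'   coordinates, `slice_y`, `weight`, `prc_end`, `phc_end`).
#' @export
plant_topography <- function(atlas, topo = topography_spec()) {
  stopifnot(inherits(atlas, "labeled_atlas"),
            inherits(topo, "topography_spec"))
  dims <- dim(atlas$labels)
  g <- topo$gradient_direction

  per_hemi_weights <- function(coords) {
    # mirror the x component for the right hemisphere so the gradient is
    # anatomically symmetric
    ctr <- colMeans(coords)
    proj <- sweep(coords, 2, ctr) %*% g
    stats::plogis(topo$mixing_steepness * as.vector(proj))
  }

  ec_vox <- atlas_voxels(atlas, "EC")
  ec_coords <- .vox_coords(ec_vox, dims)
  hemi <- atlas$hemisphere[as.character(ec_vox)]
  w <- numeric(length(ec_vox))
  for (h in unique(hemi)) {
    sel <- hemi == h
    cc <- ec_coords[sel, , drop = FALSE]
    if (h == "R") cc[, 1] <- -cc[, 1]
    w[sel] <- per_hemi_weights(cc)
  }
  ec <- data.frame(voxel = ec_vox, x = ec_coords[, 1], y = ec_coords[, 2],
                   z = ec_coords[, 3], weight = w,
                   label = ifelse(w > 0.5, "PHC", "PRC"),
                   hemisphere = unname(hemi))

  # Subiculum transverse weights from the per-slice transverse ordering.
  # For the mirrored hemisphere the stored ordering runs medial-first, so
  # it is reversed to keep "proximal" on the lateral side.
  sub_rows <- list()
  for (h in names(atlas$slice_axes)) {
    for (sl in atlas$slice_axes[[h]]$SUB) {
      if (h == "R") sl <- sl[rev(seq_len(nrow(sl))), , drop = FALSE]
      m <- nrow(sl)
      pos <- seq_len(m) - (m + 1) / 2
      sub_rows[[length(sub_rows) + 1L]] <-
        data.frame(voxel = .coords_vox(sl, dims), x = sl[, 1], y = sl[, 2],
                   z = sl[, 3],
                   weight = stats::plogis(topo$sub_transverse_steepness * pos))
    }
  }
  sub <- do.call(rbind, sub_rows)
  rownames(sub) <- NULL
  sub$slice_y <- sub$y
  ys <- sort(unique(sub$slice_y))
  k <- topo$end_slices
  if (2L * k > length(ys))
    stop(sprintf(paste0("end_slices = %d overlaps: the subiculum has only ",
                        "%d coronal slices"), k, length(ys)), call. = FALSE)
  ant <- tail(ys, k); post <- head(ys, k)
  sub$prc_end <- sub$slice_y %in% ant
  sub$phc_end <- sub$slice_y %in% post
  sub$hemisphere <- unname(atlas$hemisphere[as.character(sub$voxel)])

  structure(list(ec = ec, sub = sub, spec = topo), class = "ground_truth")
}
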