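#' Region codes used by the labeled atlas
#'
#' Integer label codes for the synthetic medial temporal lobe atlas:
#' background, entorhinal cortex (EC), perirhinal cortex (PRC),
#' parahippocampal cortex (PHC), subiculum (SUB), white matter (WM) and
#' cerebrospinal fluid (CSF).
#' @export
REGION_CODES <- c(background = 0L, EC = 1L, PRC = 2L, PHC = 3L,
                  SUB = 4L, WM = 5L, CSF = 6L)

#' Atlas geometry specification
#'
#' Describes the grid and region layout of the synthetic common-space
#' atlas.  Axis conventions are fixed: index x increases lateral to
#' medial, index y increases posterior to anterior, and index z increases
#' ventral to dorsal, all relative to the hippocampal long axis (coronal
#' slices are fixed-y planes orthogonal to that axis).
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size Isotropic voxel edge in mm (default 0.8, the
#'   acquisition resolution the template emulates).
#' @param region_extents Optional named list overriding derived region
#'   sizing (see Details).  Entries: `ec_slices`, `sub_slices`,
#'   `ec_halfwidth`, `ec_thickness`.
#' @param bilateral If `TRUE` the single-hemisphere geometry is duplicated,
#'   mirrored in x, on a grid twice as wide; hemispheres are then analyzed
#'   independently.
#' @return An object of class `atlas_spec`.
#' @details Region extents scale with the grid so that the entorhinal
#'   strip keeps at least 10 coronal slices of 3--11 voxels each and the
#'   subiculum stays elongated along y.  A background corridor of at least
#'   two voxels separates the PRC seed from the EC so that seed-border
#'   erosion has a well-defined geometry.
#' @export
atlas_spec <- function(grid_shape = c(40L, 60L, 24L), voxel_size = 0.8,
                       region_extents = list(), bilateral = FALSE) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(!is.finite(grid_shape)) ||
      any(grid_shape <= 0L))
    stop("grid_shape must be three strictly positive integers", call. = FALSE)
  .assert_scalar_number(voxel_size, "voxel_size")
  if (voxel_size <= 0) stop("voxel_size must be positive", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 region_extents = region_extents,
                 bilateral = isTRUE(bilateral)),
            class = "atlas_spec")
}

# Order voxels of one coronal slice along its transverse direction: the
# first principal axis of the in-slice (x, z) coordinates, sign-oriented so
# that increasing order runs lateral -> medial (x-increasing).  Ties are
# broken by x then z, deterministically.
.order_transverse <- function(xz) {
  xz <- as.matrix(xz)
  if (nrow(xz) == 1L) return(1L)
  ctr <- sweep(xz, 2, colMeans(xz))
  cv <- crossprod(ctr) / (nrow(xz) - 1)
  pc <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (pc[1] < 0 || (pc[1] == 0 && pc[2] < 0)) pc <- -pc
  proj <- ctr %*% pc
  order(proj, xz[, 1], xz[, 2])
}

.slice_axes_for <- function(coords) {
  ys <- sort(unique(coords[, 2]))
  out <- lapply(ys, function(y) {
    sl <- coords[coords[, 2] == y, , drop = FALSE]
    sl[.order_transverse(sl[, c(1, 3), drop = FALSE]), , drop = FALSE]
  })
  names(out) <- as.character(ys)
  out
}

.place_block <- function(xr, yr, zr) {
  as.matrix(expand.grid(x = xr, y = yr, z = zr))
}

.hemi_geometry <- function(grid, ext) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  hw <- if (!is.null(ext$ec_halfwidth)) ext$ec_halfwidth else
    if (nx >= 20) 2L else 1L
  tz <- if (!is.null(ext$ec_thickness)) ext$ec_thickness else
    if (nz >= 16) 2L else 1L
  n_ec <- if (!is.null(ext$ec_slices)) ext$ec_slices else
    max(10L, round(0.43 * ny))
  n_sub <- if (!is.null(ext$sub_slices)) ext$sub_slices else
    max(10L, floor(0.55 * ny))
  y_ant <- ny - max(2L, round(0.1 * ny))
  y0_ec <- y_ant - n_ec + 1L
  x_lat <- max(hw + 4L, round(0.25 * nx))
  x_med <- round(0.5 * nx)
  zc <- round(0.55 * nz)
  dz <- if (nz >= 16) 2L else 1L

  fail <- function(what)
    stop(sprintf("atlas regions cannot be placed in a %dx%dx%d grid (%s)",
                 nx, ny, nz, what), call. = FALSE)
  if (y0_ec < 8L) fail("EC strip does not fit along y")
  if (x_med + hw + 4L + 2L * hw > nx) fail("EC/SUB do not fit along x")
  if (zc + tz - 1L > nz || zc - dz - 1L < 1L) fail("EC does not fit along z")

  # EC: elongated strip, anterior end lateral+ventral, posterior end
  # medial+dorsal, so the anterior-lateral -> posterior-medial axis of the
  # planted gradient has real spatial extent.
  ec <- do.call(rbind, lapply(seq_len(n_ec), function(j) {
    u <- (j - 1) / max(1L, n_ec - 1L)        # 0 posterior -> 1 anterior
    y <- y0_ec + j - 1L
    cx <- round(x_med - u * (x_med - x_lat))
    cz <- zc - round(u * dz)
    .place_block((cx - hw):(cx + hw), y, cz:(cz + tz - 1L))
  }))

  # PRC: anterior-lateral block with a 2-voxel background corridor to EC.
  prc_x2 <- x_lat - hw - 3L
  if (prc_x2 < 1L) fail("no room lateral of EC for the PRC")
  prc_x1 <- max(1L, prc_x2 - 2L)
  prc_len <- max(6L, ceiling(0.45 * n_ec))
  prc_y <- (y_ant - prc_len + 1L):y_ant
  prc_z <- max(1L, zc - dz - 1L):min(nz, zc - dz + 1L)
  prc <- .place_block(prc_x1:prc_x2, prc_y, prc_z)

  # PHC: posterior of EC, 2-voxel corridor in y.
  phc_len <- max(4L, round(0.12 * ny))
  phc_y2 <- y0_ec - 3L
  phc_y1 <- phc_y2 - phc_len + 1L
  if (phc_y1 < 1L) fail("no room posterior of EC for the PHC")
  phc <- .place_block((x_med - hw):(x_med + hw), phc_y1:phc_y2,
                      max(1L, zc - 1L):min(nz, zc + 1L))

  # Subiculum: elongated along y, medial of the EC.
  sub_x0 <- x_med + hw + 4L
  y0_sub <- y_ant - n_sub + 1L
  if (y0_sub < 2L) fail("subiculum does not fit along y")
  sub <- do.call(rbind, lapply(seq_len(n_sub), function(j) {
    y <- y0_sub + j - 1L
    .place_block(sub_x0:(sub_x0 + 2L * hw), y, zc:(zc + tz - 1L))
  }))

  # WM / CSF confound compartments in opposite corners.
  if (nz < 10L) fail("no room for WM/CSF compartments along z")
  wm <- .place_block(2L:min(5L, nx), 2L:6L, (nz - 2L):nz)
  csf <- .place_block((nx - 4L):(nx - 1L), 2L:6L, 1L:3L)

  list(EC = ec, PRC = prc, PHC = phc, SUB = sub, WM = wm, CSF = csf)
}

#' Build a labeled common-space atlas
#'
#' Places disjoint EC, PRC, PHC, subiculum, WM and CSF regions on the grid
#' described by `spec`.  The EC and subiculum are elongated along the
#' longitudinal (y) axis and carry, for every coronal slice, an ordered
#' list of member voxels sorted along the slice's transverse direction.
#'
#' @param spec An [atlas_spec()].
#' @param seed Integer; recorded for provenance.  The geometry is fully
#'   deterministic, so repeated calls with any seed agree.
#' @return An object of class `labeled_atlas` with fields `labels`
#'   (3-D integer array), `codes`, `voxel_size`, `slice_axes` (per-slice
#'   transverse orderings for EC and SUB), `hemisphere` (per-voxel L/R for
#'   bilateral atlases) and `spec`.
#' @export
make_atlas <- function(spec = atlas_spec(), seed = 1L) {
  stopifnot(inherits(spec, "atlas_spec"))
  grid <- spec$grid_shape
  geo <- .hemi_geometry(grid, spec$region_extents)

  if (spec$bilateral) {
    nx <- grid[1]
    grid <- c(2L * nx, grid[2], grid[3])
    geo_l <- geo
    geo_r <- lapply(geo, function(m) {
      m[, 1] <- 2L * nx + 1L - m[, 1]; m
    })
    geo <- Map(rbind, geo_l, geo_r)
    hemi_of <- function(m) ifelse(m[, 1] <= nx, "L", "R")
    slice_axes <- list(
      L = list(EC = .slice_axes_for(geo_l$EC),
               SUB = .slice_axes_for(geo_l$SUB)),
      R = list(EC = .slice_axes_for(geo_r$EC),
               SUB = .slice_axes_for(geo_r$SUB)))
  } else {
    hemi_of <- function(m) rep("L", nrow(m))
    slice_axes <- list(
      L = list(EC = .slice_axes_for(geo$EC),
               SUB = .slice_axes_for(geo$SUB)))
  }

  labels <- array(0L, dim = grid)
  hemisphere <- character(0)
  all_idx <- integer(0)
  for (rg in names(geo)) {
    m <- geo[[rg]]
    if (any(m < 1L) || any(sweep(m, 2, grid, ">")))
      stop("atlas regions cannot be placed in grid (region out of bounds)",
           call. = FALSE)
    idx <- .coords_vox(m, grid)
    if (any(labels[idx] != 0L))
      stop(sprintf("atlas regions overlap (%s)", rg), call. = FALSE)
    labels[idx] <- REGION_CODES[[rg]]
    all_idx <- c(all_idx, idx)
    hemisphere <- c(hemisphere, hemi_of(m))
  }
  names(hemisphere) <- as.character(all_idx)

  structure(list(labels = labels, codes = REGION_CODES,
                 voxel_size = spec$voxel_size, slice_axes = slice_axes,
                 hemisphere = hemisphere, spec = spec, seed = seed),
            class = "labeled_atlas")
}

#' Logical mask for one atlas region
#' @param atlas A `labeled_atlas`.
#' @param region Region name, one of `names(REGION_CODES)` except
#'   background, or a vector of names (union).
#' @return Logical array of the atlas grid shape.
#' @export
atlas_mask <- function(atlas, region) {
  stopifnot(inherits(atlas, "labeled_atlas"))
  bad <- setdiff(region, names(atlas$codes))
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  array(atlas$labels %in% atlas$codes[region], dim(atlas$labels))
}

#' Linear voxel indices for one atlas region
#' @inheritParams atlas_mask
#' @return Integer vector of linear indices into the label grid.
#' @export
atlas_voxels <- function(atlas, region) {
  which(atlas_mask(atlas, region))
}

#' @export
print.labeled_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("labeled_atlas: %dx%dx%d grid, %.2g mm voxels\n",
              d[1], d[2], d[3], x$voxel_size))
  tb <- table(factor(x$labels[x$labels > 0],
                     levels = x$codes[-1], labels = names(x$codes)[-1]))
  for (nm in names(tb)) cat(sprintf("  %-4s %5d voxels\n", nm, tb[[nm]]))
  invisible(x)
}
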