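#' Split an elongated ROI into longitudinal halves
#'
#' Coronal (fixed-y) slices are ordered along y and a cut between slices
#' is chosen so the two halves' voxel counts are as equal as possible;
#' no slice is divided.  The anterior half is the larger-y side; when two
#' cuts tie, the one giving more slices to the anterior half is used.
#'
#' @param coords n x 3 integer coordinate matrix of the ROI voxels (or a
#'   data frame with columns `x`, `y`, `z`).
#' @return Data frame with `voxel_row`, `slice_y`, `longitudinal`
#'   (factor `anterior`/`posterior`).
#' @export
split_longitudinal <- function(coords) {
  co <- .coords_df(coords)
  ys <- sort(unique(co$y))   # posterior -> anterior
  if (length(ys) < 2L)
    stop("ROI spans a single coronal slice; longitudinal split undefined",
         call. = FALSE)
  counts <- vapply(ys, function(y) sum(co$y == y), integer(1))
  total <- sum(counts)
  # cut after slice k (posterior side gets slices 1..k of increasing y)
  post_counts <- cumsum(counts)[-length(counts)]
  imbalance <- abs(total - 2 * post_counts)
  k <- which(imbalance == min(imbalance))
  k <- k[1L]   # smallest posterior side among ties -> more slices anterior
  post_ys <- ys[seq_len(k)]
  data.frame(voxel_row = seq_len(nrow(co)), slice_y = co$y,
             longitudinal = factor(ifelse(co$y %in% post_ys, "posterior",
                                          "anterior"),
                                   levels = c("anterior", "posterior")))
}

.coords_df <- function(coords) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y", "z") %in% names(coords)))
    data.frame(x = coords$x, y = coords$y, z = coords$z)
  } else {
    coords <- as.matrix(coords)
    data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  }
}

#' Split each coronal slice of an ROI into transverse bins
#'
#' Within each fixed-y slice, voxels are ordered along the slice's
#' transverse axis (first principal axis of the in-slice coordinates,
#' oriented lateral to medial) and divided into `n_bins` contiguous
#' equal-count bins; remainder voxels are assigned one each to the most
#' lateral bins.  Bin 1 is most lateral (proximal), bin `n_bins` most
#' medial (distal).
#'
#' @inheritParams split_longitudinal
#' @param n_bins Number of transverse bins (2 for halves, 5 for the
#'   profile quintiles).
#' @return Data frame with `voxel_row`, `slice_y`, `transverse_rank`
#'   (order within slice), `transverse_bin` (integer 1..n_bins).
#' @export
split_transverse_per_slice <- function(coords, n_bins = 2L) {
  co <- .coords_df(coords)
  n_bins <- as.integer(n_bins)
  out <- data.frame(voxel_row = seq_len(nrow(co)), slice_y = co$y,
                    transverse_rank = NA_integer_,
                    transverse_bin = NA_integer_)
  for (y in sort(unique(co$y))) {
    rows <- which(co$y == y)
    m <- length(rows)
    if (m < n_bins)
      stop(sprintf("slice y = %d has %d voxels, fewer than %d bins",
                   y, m, n_bins), call. = FALSE)
    ord <- .order_transverse(cbind(co$x[rows], co$z[rows]))
    base <- m %/% n_bins; rem <- m %% n_bins
    sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
    bins <- rep(seq_len(n_bins), times = sizes)
    out$transverse_rank[rows[ord]] <- seq_len(m)
    out$transverse_bin[rows[ord]] <- bins
  }
  out
}

#' Full section assignment for an elongated ROI
#'
#' Combines the longitudinal half split, the per-slice transverse half
#' split, and (when every slice has at least 5 voxels) the per-slice
#' transverse quintiles.
#'
#' @param atlas A `labeled_atlas`.
#' @param roi `"EC"` or `"SUB"`.
#' @param quintiles Compute the 5-bin transverse assignment too?
#' @return An object of class `section_assignment`: data frame with
#'   `voxel`, `x`, `y`, `z`, `slice_y`, `longitudinal`,
#'   `transverse_half` (factor `lateral`/`medial`), `transverse_rank`
#'   and optionally `transverse_quintile`.
#' @export
section_assignment <- function(atlas, roi = "EC", quintiles = TRUE) {
  vox <- atlas_voxels(atlas, roi)
  co <- .vox_coords(vox, dim(atlas$labels))
  lng <- split_longitudinal(co)
  hlv <- split_transverse_per_slice(co, 2L)
  out <- data.frame(voxel = vox, x = co[, 1], y = co[, 2], z = co[, 3],
                    slice_y = lng$slice_y,
                    longitudinal = lng$longitudinal,
                    transverse_half = factor(
                      c("lateral", "medial")[hlv$transverse_bin],
                      levels = c("lateral", "medial")),
                    transverse_rank = hlv$transverse_rank)
  if (quintiles) {
    qnt <- split_transverse_per_slice(co, 5L)
    out$transverse_quintile <- qnt$transverse_bin
  }
  structure(out, class = c("section_assignment", "data.frame"))
}

#' Cell means of connectivity over ROI sections
#'
#' Unweighted mean of the Fisher-z values within each
#' (longitudinal x transverse) section, one row per cell.
#'
#' @param map A `fisher_zmap` covering (at least) the sectioned ROI.
#' @param sections A `section_assignment`.
#' @param subject,seed Identifiers for the output rows; defaults come
#'   from the map.
#' @return Data frame with `subject`, `seed`, `longitudinal`,
#'   `transverse`, `value`.
#' @export
section_means <- function(map, sections, subject = map$subject_id,
                          seed = map$seed_id) {
  stopifnot(inherits(map, "fisher_zmap"))
  pos <- match(sections$voxel, map$voxels)
  if (anyNA(pos))
    stop("map does not cover every sectioned voxel", call. = FALSE)
  vals <- map$values[pos]
  cells <- expand.grid(longitudinal = levels(sections$longitudinal),
                       transverse = levels(sections$transverse_half),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- sections$longitudinal == cells$longitudinal[i] &
      sections$transverse_half == cells$transverse[i]
    if (!any(sel))
      stop(sprintf("empty section cell (%s, %s)", cells$longitudinal[i],
                   cells$transverse[i]), call. = FALSE)
    data.frame(subject = subject, seed = seed,
               longitudinal = cells$longitudinal[i],
               transverse = cells$transverse[i], value = mean(vals[sel]))
  })
  do.call(rbind, rows)
}

# per-subject contrast scores for a +-1 contrast over the 2x2x2 cells
.contrast_scores <- function(tab, effect) {
  f <- list(seed = tab$seed, longitudinal = tab$longitudinal,
            transverse = tab$transverse)
  f <- lapply(f, function(v) {
    lv <- sort(unique(as.character(v)))
    ifelse(as.character(v) == lv[1], 1, -1)
  })
  parts <- strsplit(effect, ":")[[1]]
  cc <- rep(1, nrow(tab))
  for (p in parts) cc <- cc * f[[p]]
  tapply(tab$value * cc, tab$subject, sum)
}

#' Within-subject 2x2x2 factorial ANOVA on section means
#'
#' All-within repeated-measures ANOVA with factors seed, longitudinal
#' section and transverse section, each at two levels.  Every effect has
#' one numerator df, so its F equals the squared one-sample t of the
#' per-subject +-1 contrast score, with df = (1, n - 1); this identity is
#' used directly.
#'
#' @param table Cell-means data frame with columns `subject`, `seed`,
#'   `longitudinal`, `transverse`, `value`; every subject needs all 8
#'   cells.
#' @return Data frame with `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2x2 <- function(table) {
  need <- c("subject", "seed", "longitudinal", "transverse", "value")
  if (!all(need %in% names(table)))
    stop("table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  tab <- table
  counts <- table(tab$subject)
  if (any(counts != 8L)) {
    bad <- names(counts)[counts != 8L]
    stop("incomplete cells for subject(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  effects <- c("seed", "longitudinal", "transverse",
               "seed:longitudinal", "seed:transverse",
               "longitudinal:transverse", "seed:longitudinal:transverse")
  n <- length(unique(tab$subject))
  rows <- lapply(effects, function(ef) {
    sc <- .contrast_scores(tab, ef)
    m <- mean(sc); s <- sd(sc)
    Fv <- if (s == 0) {
      if (m == 0) 0 else Inf
    } else (m / (s / sqrt(n)))^2
    data.frame(effect = ef, F = Fv, df1 = 1L, df2 = n - 1L,
               p = pf(Fv, 1, n - 1, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired follow-up t-test between two cells
#'
#' Two-sided paired t-test across subjects on the mean values of two
#' cells.  A cell is described by naming any subset of the factors, e.g.
#' `list(seed = "PRC", longitudinal = "anterior")`; rows matching the
#' description are averaged within subject first.
#'
#' @param table Cell-means data frame (see [rm_anova_2x2x2()]).
#' @param cell_a,cell_b Named lists selecting the two cells.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_followup <- function(table, cell_a, cell_b) {
  pick <- function(cell) {
    sel <- rep(TRUE, nrow(table))
    for (nm in names(cell)) sel <- sel & table[[nm]] == cell[[nm]]
    if (!any(sel)) stop("cell selects no rows", call. = FALSE)
    tapply(table$value[sel], table$subject[sel], mean)
  }
  a <- pick(cell_a); b <- pick(cell_b)
  if (!identical(names(a), names(b)))
    stop("cells cover different subjects", call. = FALSE)
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = unname(tt), df = n - 1L,
       p = 2 * pt(abs(tt), n - 1L, lower.tail = FALSE),
       mean_diff = unname(mean(d)))
}

#' Across-subject slice or transverse-bin profiles
#'
#' Longitudinal profiles give, per coronal slice, the across-subject mean
#' and SEM of the within-slice mean Fisher z, per seed; transverse
#' profiles pool each quintile bin across slices.
#'
#' @param maps Named list: seed id -> list of per-subject `fisher_zmap`.
#' @param sections A `section_assignment` (with quintiles for the
#'   transverse axis).
#' @param axis `"longitudinal"` or `"transverse"`.
#' @return Data frame with `seed`, `position`, `mean`, `sem`, `n`.
#' @export
slice_profiles <- function(maps, sections, axis = c("longitudinal",
                                                    "transverse")) {
  axis <- match.arg(axis)
  if (axis == "transverse" && is.null(sections$transverse_quintile))
    stop("sections carry no quintile assignment", call. = FALSE)
  group <- if (axis == "longitudinal") sections$slice_y else
    sections$transverse_quintile
  positions <- sort(unique(group))
  rows <- list()
  for (seed in names(maps)) {
    per_subj <- vapply(maps[[seed]], function(m) {
      pos <- match(sections$voxel, m$voxels)
      if (anyNA(pos)) stop("map does not cover the ROI", call. = FALSE)
      vals <- m$values[pos]
      vapply(positions, function(g) mean(vals[group == g]), numeric(1))
    }, numeric(length(positions)))
    per_subj <- matrix(per_subj, nrow = length(positions))
    n <- ncol(per_subj)
    rows[[seed]] <- data.frame(
      seed = seed, position = positions, mean = rowMeans(per_subj),
      sem = apply(per_subj, 1L, sd) / sqrt(n), n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired contrast over the end slices of an ROI
#'
#' Per subject, mean Fisher z over the `k` most anterior (or posterior)
#' coronal slices for each of two seeds, then a two-sided paired t-test
#' across subjects.
#'
#' @param maps_a,maps_b Subject-matched lists of `fisher_zmap` for the
#'   two seeds.
#' @param sections A `section_assignment` of the ROI.
#' @param k Number of end slices (default 8).
#' @param end `"anterior"` (largest y) or `"posterior"`.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
end_slices_contrast <- function(maps_a, maps_b, sections, k = 8L,
                                end = c("anterior", "posterior")) {
  end <- match.arg(end)
  ys <- sort(unique(sections$slice_y))
  if (k > length(ys))
    stop(sprintf("ROI has %d slices, fewer than k = %d", length(ys), k),
         call. = FALSE)
  pick_ys <- if (end == "anterior") tail(ys, k) else head(ys, k)
  sel <- sections$slice_y %in% pick_ys
  vox <- sections$voxel[sel]
  subj_mean <- function(m) {
    pos <- match(vox, m$voxels)
    if (anyNA(pos)) stop("map does not cover the ROI", call. = FALSE)
    mean(m$values[pos])
  }
  a <- vapply(maps_a, subj_mean, numeric(1))
  b <- vapply(maps_b, subj_mean, numeric(1))
  if (length(a) != length(b)) stop("subject lists differ", call. = FALSE)
  d <- a - b
  n <- length(d)
  tt <- if (sd(d) == 0) { if (mean(d) == 0) 0 else Inf * sign(mean(d)) }
  else mean(d) / (sd(d) / sqrt(n))
  list(t = tt, df = n - 1L,
       p = if (is.finite(tt)) 2 * pt(abs(tt), n - 1L, lower.tail = FALSE)
       else ifelse(tt == 0, 1, 0),
       mean_diff = mean(d))
}

#' Interaction of connectivity-difference profiles along the long axis
#'
#' Tests whether the anterior-versus-posterior profile of the EC-subregion
#' connectivity difference (al-EC minus pm-EC) differs from that of the
#' neocortical-seed difference (PRC minus PHC) over the same subiculum
#' sections: a 2x2 within-subject ANOVA of seed-pair x longitudinal
#' section, whose interaction F equals the squared paired t of the
#' difference of differences.
#'
#' @param ec_table Cell-means table for the al-EC / pm-EC seeds over the
#'   subiculum (columns `subject`, `seed`, `longitudinal`, `value`; a
#'   `transverse` column, if present, is averaged over).
#' @param ctx_table Same structure for the PRC / PHC seeds.
#' @return One-row data frame: `effect = "seed_pair:longitudinal"`, `F`,
#'   `df1`, `df2`, `p`.
#' @export
delta_interaction <- function(ec_table, ctx_table) {
  # seed-pair differences are taken in first-appearance order of the
  # input tables (e.g. al-EC minus pm-EC, PRC minus PHC); the
  # interaction F is invariant to flipping both pairs but not one, so
  # the caller's row order defines the signs
  seeds_ec <- unique(as.character(ec_table$seed))
  seeds_cx <- unique(as.character(ctx_table$seed))
  if (length(seeds_ec) != 2L || length(seeds_cx) != 2L)
    stop("each table needs exactly two seeds", call. = FALSE)
  collapse <- function(tab) {
    aggregate(value ~ subject + seed + longitudinal, data = tab,
              FUN = mean)
  }
  ec <- collapse(ec_table); cx <- collapse(ctx_table)
  subs <- sort(unique(as.character(ec$subject)))
  if (!identical(subs, sort(unique(as.character(cx$subject)))))
    stop("tables cover different subjects", call. = FALSE)
  delta <- function(tab, seeds, subject, longitudinal) {
    sl <- tab[tab$subject == subject & tab$longitudinal == longitudinal, ]
    sl$value[sl$seed == seeds[1]] - sl$value[sl$seed == seeds[2]]
  }
  dd <- vapply(subs, function(s) {
    (delta(ec, seeds_ec, s, "anterior") -
       delta(ec, seeds_ec, s, "posterior")) -
      (delta(cx, seeds_cx, s, "anterior") -
         delta(cx, seeds_cx, s, "posterior"))
  }, numeric(1))
  n <- length(dd)
  Fv <- if (sd(dd) == 0) { if (mean(dd) == 0) 0 else Inf }
  else (mean(dd) / (sd(dd) / sqrt(n)))^2
  data.frame(effect = "seed_pair:longitudinal", F = Fv, df1 = 1L,
             df2 = n - 1L, p = pf(Fv, 1, n - 1, lower.tail = FALSE))
}
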