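#' Stack subject Fisher-z maps into a voxel-by-subject matrix
#'
#' @param maps List of `fisher_zmap` objects over identical voxel sets.
#' @return V x n numeric matrix with the common `voxels` as an attribute.
#' @export
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  vox <- maps[[1L]]$voxels
  for (m in maps)
    if (!identical(m$voxels, vox))
      stop("maps do not share a common target mask", call. = FALSE)
  X <- vapply(maps, function(m) m$values, numeric(length(vox)))
  attr(X, "voxels") <- vox
  X
}

.as_subject_matrix <- function(maps) {
  if (is.list(maps)) stack_maps(maps) else as.matrix(maps)
}

# One-sided normal-equivalent z of a t statistic, numerically stable in
# the tails; infinities are preserved as sentinels.
.t_to_z <- function(t, df) {
  z <- ifelse(is.finite(t),
              qnorm(pt(t, df, log.p = TRUE), log.p = TRUE), t)
  z
}

#' Voxelwise one-sample t map
#'
#' Per voxel `t = mean / (sd / sqrt(n))` across subjects, with the
#' one-sided normal-equivalent z.  Voxels with zero variance but nonzero
#' mean get an infinite-t sentinel (excluded from clustering and listed
#' under `qc_zero_variance`); all-zero voxels get `t = 0`.
#'
#' @param maps List of `fisher_zmap` objects (common mask) or a V x n
#'   matrix of subject values.
#' @param contrast_id Label stored with the result.
#' @return An object of class `group_stat_map`: `t`, `z` (normal
#'   equivalent), `df` (= n - 1), `n`, `voxels`, `contrast_id`,
#'   `qc_zero_variance`.
#' @export
one_sample_t <- function(maps, contrast_id = "one_sample") {
  X <- .as_subject_matrix(maps)
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 subject maps", call. = FALSE)
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(0, (rowSums(X^2) - n * mu^2) / (n - 1)))
  tt <- numeric(nrow(X))
  zero <- sdv == 0
  tt[!zero] <- mu[!zero] / (sdv[!zero] / sqrt(n))
  tt[zero & mu > 0] <- Inf
  tt[zero & mu < 0] <- -Inf
  structure(list(t = tt, z = .t_to_z(tt, n - 1L), df = n - 1L, n = n,
                 voxels = attr(X, "voxels"), contrast_id = contrast_id,
                 qc_zero_variance = which(zero & mu != 0)),
            class = "group_stat_map")
}

#' Voxelwise paired t map
#'
#' One-sample t map of the per-subject differences `a - b`.  Swapping the
#' arguments negates the map exactly.
#'
#' @param maps_a,maps_b Subject-matched lists of `fisher_zmap` (or V x n
#'   matrices, columns in the same subject order).
#' @param contrast_id Label stored with the result.
#' @return A `group_stat_map` of the differences.
#' @export
paired_t <- function(maps_a, maps_b, contrast_id = "paired") {
  A <- .as_subject_matrix(maps_a); B <- .as_subject_matrix(maps_b)
  if (!identical(dim(A), dim(B)))
    stop("subject lists must be matched in length and mask", call. = FALSE)
  if (!is.null(attr(A, "voxels")) &&
      !identical(attr(A, "voxels"), attr(B, "voxels")))
    stop("paired maps do not share a target mask", call. = FALSE)
  if (is.list(maps_a) && is.list(maps_b)) {
    sa <- vapply(maps_a, function(m) m$subject_id, character(1))
    sb <- vapply(maps_b, function(m) m$subject_id, character(1))
    if (!identical(sa, sb)) stop("subject order mismatch", call. = FALSE)
  }
  D <- A - B
  attr(D, "voxels") <- attr(A, "voxels")
  one_sample_t(D, contrast_id = contrast_id)
}

# 26-connected neighbor index lists for the voxels of a mask.
.mask_adjacency <- function(voxels, dim) {
  co <- .vox_coords(voxels, dim)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lut <- seq_along(voxels)
  names(lut) <- key(co)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr <- vector("list", length(voxels))
  for (r in seq_len(nrow(offs))) {
    sh <- sweep(co, 2, offs[r, ], "+")
    hit <- lut[key(sh)]
    ok <- !is.na(hit)
    if (any(ok)) {
      w <- which(ok)
      for (i in seq_along(w)) nbr[[w[i]]] <- c(nbr[[w[i]]], hit[w[i]])
    }
  }
  nbr
}

# Label connected components of a logical vector over a mask with
# precomputed adjacency; returns integer labels (0 = below threshold).
.cc_label <- function(supra, nbr) {
  lab <- integer(length(supra))
  cur <- 0L
  for (s in which(supra)) {
    if (lab[s]) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (u in nbr[[v]]) {
        if (supra[u] && !lab[u]) {
          lab[u] <- cur
          stack <- c(stack, u)
        }
      }
    }
  }
  lab
}

.max_cluster_size <- function(supra, nbr) {
  lab <- .cc_label(supra, nbr)
  if (!any(lab > 0L)) 0L else max(tabulate(lab))
}

#' Cluster-extent thresholding with a sign-flip permutation null
#'
#' Suprathreshold clusters are 26-connected components of
#' `z > z_thresh`.  The family-wise null distribution of the maximum
#' cluster size is built by sign-flipping the subject maps (for a paired
#' contrast, pass the per-subject difference maps: flipping a difference
#' is identical to swapping the condition labels within that subject).
#' Cluster `p_fwe = (1 + #(null max >= size)) / (1 + n_perm)`, so p-values
#' respect the permutation floor `1/(1+n_perm)`.
#'
#' @param map A `group_stat_map` (the observed statistic map).
#' @param subject_maps The per-subject maps (list of `fisher_zmap` or
#'   V x n matrix) that produced `map`; differences for a paired contrast.
#' @param dim Grid shape (needed to form the 26-neighborhood); defaults to
#'   the attribute stored on `subject_maps` if present.
#' @param z_thresh Cluster-forming threshold on the normal-equivalent z
#'   (default 2.3).
#' @param alpha Cluster-level family-wise alpha (default 0.05).
#' @param n_perm Number of sign-flip permutations (default 1000; fewer
#'   than 100 is refused).
#' @param seed RNG seed for the sign flips.
#' @return An object of class `cluster_table`: data frame of significant
#'   clusters (`cluster_id`, `size`, `peak_z`, `x`, `y`, `z`, `p_fwe`),
#'   with attributes `membership` (list of voxel indices per significant
#'   cluster), `all_clusters` and `null_max_size`.
#' @export
cluster_threshold <- function(map, subject_maps, dim, z_thresh = 2.3,
                              alpha = 0.05, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(map, "group_stat_map"))
  if (n_perm < 100L)
    stop("n_perm < 100 gives an unusably coarse null", call. = FALSE)
  X <- .as_subject_matrix(subject_maps)
  n <- ncol(X)
  vox <- map$voxels
  if (is.null(vox)) vox <- attr(X, "voxels")
  if (is.null(vox)) stop("voxel indices unavailable", call. = FALSE)
  nbr <- .mask_adjacency(vox, dim)

  z <- map$z
  z[!is.finite(map$t)] <- -Inf   # zero-variance sentinels never cluster
  lab <- .cc_label(z > z_thresh, nbr)

  # permutation null of the maximum cluster size
  set.seed(as.integer(seed))
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  ss <- rowSums(X^2)
  finite_rows <- apply(is.finite(X), 1L, all)
  null_max <- integer(n_perm)
  Mu <- X %*% t(S) / n                       # V x n_perm permuted means
  for (p in seq_len(n_perm)) {
    mu <- Mu[, p]
    sdv <- sqrt(pmax(0, (ss - n * mu^2) / (n - 1)))
    tp <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
    zp <- .t_to_z(tp, n - 1L)
    zp[!finite_rows] <- -Inf
    null_max[p] <- .max_cluster_size(zp > z_thresh, nbr)
  }

  if (!any(lab > 0L)) {
    empty <- data.frame(cluster_id = integer(0), size = integer(0),
                        peak_z = numeric(0), x = integer(0), y = integer(0),
                        z = integer(0), p_fwe = numeric(0))
    return(structure(empty, membership = list(), all_clusters = empty,
                     null_max_size = null_max,
                     class = c("cluster_table", "data.frame")))
  }
  sizes <- tabulate(lab)
  co <- .vox_coords(vox, dim)
  rows <- lapply(seq_along(sizes), function(k) {
    members <- which(lab == k)
    pk <- members[which.max(z[members])]
    data.frame(cluster_id = k, size = sizes[k], peak_z = z[pk],
               x = co[pk, 1], y = co[pk, 2], z.1 = co[pk, 3],
               p_fwe = (1 + sum(null_max >= sizes[k])) / (1 + n_perm))
  })
  tb <- do.call(rbind, rows)
  names(tb)[names(tb) == "z.1"] <- "z"
  ord <- order(-tb$size)
  tb <- tb[ord, , drop = FALSE]
  membership_all <- lapply(tb$cluster_id, function(k) vox[lab == k])
  keep <- tb$p_fwe < alpha
  out <- tb[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, membership = membership_all[keep], all_clusters = tb,
            null_max_size = null_max,
            class = c("cluster_table", "data.frame"))
}

#' Group connectivity-preference map
#'
#' Labels every voxel of a paired statistic map by the sign of its t
#' value: positive (including the exact tie `t = 0`) is labeled
#' PRC-preferring, negative PHC-preferring.
#'
#' @param paired A `group_stat_map` from [paired_t()] with the PRC-minus-
#'   PHC orientation.
#' @return An object of class `preference_map`: data frame with `voxel`,
#'   `label` (`"PRC"`/`"PHC"`), `magnitude` (absolute t).
#' @export
preference_map <- function(paired) {
  stopifnot(inherits(paired, "group_stat_map"))
  structure(data.frame(voxel = paired$voxels,
                       label = ifelse(paired$t >= 0, "PRC", "PHC"),
                       magnitude = abs(paired$t)),
            class = c("preference_map", "data.frame"))
}

#' Per-subject connectivity-preference map
#'
#' The single-subject analogue of [preference_map()]: each voxel is
#' labeled by the sign of that subject's PRC-minus-PHC Fisher-z
#' difference (ties to PRC).  These per-subject labelings feed the
#' coordinate classifier.
#'
#' @param zmap_prc,zmap_phc The subject's `fisher_zmap` for each seed,
#'   over the same voxels.
#' @return A `preference_map` data frame with a `subject_id` attribute.
#' @export
subject_preference_map <- function(zmap_prc, zmap_phc) {
  stopifnot(inherits(zmap_prc, "fisher_zmap"),
            inherits(zmap_phc, "fisher_zmap"))
  if (!identical(zmap_prc$voxels, zmap_phc$voxels))
    stop("seed maps cover different voxels", call. = FALSE)
  d <- zmap_prc$values - zmap_phc$values
  structure(data.frame(voxel = zmap_prc$voxels,
                       label = ifelse(d >= 0, "PRC", "PHC"),
                       magnitude = abs(d)),
            subject_id = zmap_prc$subject_id,
            class = c("preference_map", "data.frame"))
}

#' Derive EC-subregion seed masks from paired-t clusters
#'
#' The anterior-lateral EC seed is the union of significant PRC>PHC
#' clusters; the posterior-medial EC seed is the union of significant
#' PHC>PRC clusters.
#'
#' @param clusters_prc A `cluster_table` for the PRC>PHC direction.
#' @param clusters_phc A `cluster_table` for the PHC>PRC direction.
#' @param ec_voxels Integer indices of the EC mask (for validation).
#' @return A list with `al_ec` and `pm_ec` integer voxel vectors
#'   (class `seed_region_pair`).
#' @export
derive_subregion_seeds <- function(clusters_prc, clusters_phc, ec_voxels) {
  al <- sort(unique(unlist(attr(clusters_prc, "membership"))))
  pm <- sort(unique(unlist(attr(clusters_phc, "membership"))))
  if (!length(al) || !length(pm))
    stop("no significant cluster for at least one preference direction; ",
         "fall back to the classifier-predicted subregion masks",
         call. = FALSE)
  if (length(setdiff(c(al, pm), ec_voxels)))
    stop("cluster voxels outside the EC mask", call. = FALSE)
  if (length(intersect(al, pm)))
    stop("opposite-sign clusters overlap", call. = FALSE)
  structure(list(al_ec = al, pm_ec = pm), class = "seed_region_pair")
}
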