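#' Assemble coordinate samples for the preference classifier
#'
#' One sample per (voxel, subject): features are the voxel's x-y-z
#' coordinates centered on the ROI centroid (identical across subjects,
#' since all subjects live in the common space), the label is that
#' subject's connectivity preference, and the chunk is the subject.
#'
#' @param subject_maps List of per-subject `preference_map` data frames
#'   over the identical voxel set (see [subject_preference_map()]).
#' @param dim Grid shape used to convert voxel indices to coordinates.
#' @return An object of class `voxel_sample_set`: `coords` (V x 3,
#'   centered), `labels` (V x n character matrix, `"PRC"`/`"PHC"`),
#'   `subjects`, `voxels`.
#' @export
assemble_samples <- function(subject_maps, dim) {
  stopifnot(length(subject_maps) >= 2L)
  vox <- subject_maps[[1L]]$voxel
  for (m in subject_maps)
    if (!identical(m$voxel, vox))
      stop("subjects cover different voxel sets", call. = FALSE)
  labels <- vapply(subject_maps, function(m) as.character(m$label),
                   character(length(vox)))
  subjects <- vapply(seq_along(subject_maps), function(i) {
    s <- attr(subject_maps[[i]], "subject_id")
    if (is.null(s)) sprintf("sub-%02d", i) else s
  }, character(1))
  colnames(labels) <- subjects
  co <- .vox_coords(vox, dim)
  co <- sweep(co, 2, colMeans(co))
  structure(list(coords = co, labels = labels, subjects = subjects,
                 voxels = as.integer(vox)),
            class = "voxel_sample_set")
}

.labels_pm <- function(lab) ifelse(lab == "PRC", 1, -1)

# Run the leave-one-subject-out scheme for a given label matrix used in
# TRAINING; accuracy is always measured against ds$labels (the true
# labels of the held-out subject).
#
# All chunks share the same coordinates, so a fold's stacked training set
# contains every voxel n-1 times.  The hinge objective over those
# duplicates collapses exactly into per-point label counts, which the
# compiled pair solver handles directly (see src/loso_perm.cpp).
.loso_run <- function(ds, train_labels, cost) {
  n <- length(ds$subjects)
  V <- nrow(ds$coords)
  X_aug <- cbind(ds$coords, 1)
  Xt <- t(X_aug)
  is_prc <- train_labels == "PRC"
  pos_tot <- rowSums(is_prc)
  preds <- matrix(NA_character_, V, n, dimnames = list(NULL, ds$subjects))
  acc <- numeric(n)
  for (s in seq_len(n)) {
    pos <- pos_tot - is_prc[, s]
    neg <- (n - 1L) - pos
    if (all(pos == 0L) || all(neg == 0L))
      stop("training fold contains a single label", call. = FALSE)
    w <- .svm_pair_dcd_cpp(Xt, pos, neg, cost)
    scores <- X_aug %*% w
    pred <- ifelse(scores >= 0, "PRC", "PHC")
    preds[, s] <- pred
    acc[s] <- mean(pred == ds$labels[, s])
  }
  names(acc) <- ds$subjects
  list(fold_accuracy = acc, mean_accuracy = mean(acc), predictions = preds)
}

#' Leave-one-subject-out linear SVM on voxel coordinates
#'
#' For each fold, a linear support vector machine (L2-regularized hinge
#' loss, solved by dual coordinate descent) is trained on the coordinate
#' samples of all but one subject and tested on the held-out subject;
#' fold accuracy is the fraction of that subject's voxels whose predicted
#' preference matches the subject's own label.  Deterministic given the
#' sample set.
#'
#' @param ds A `voxel_sample_set`.
#' @param svm_cost SVM cost parameter C (default 1).
#' @return An object of class `loso_result`: `fold_accuracy` (per
#'   subject), `mean_accuracy`, `predictions` (V x n character matrix).
#' @export
loso_svm <- function(ds, svm_cost = 1.0) {
  stopifnot(inherits(ds, "voxel_sample_set"))
  if (length(ds$subjects) < 2L) stop("need at least 2 chunks", call. = FALSE)
  res <- .loso_run(ds, ds$labels, svm_cost)
  structure(c(res, list(svm_cost = svm_cost, truth = ds$labels)),
            class = "loso_result")
}

#' Permutation null for the LOSO classification accuracy
#'
#' Each iteration relabels the samples within every training chunk by a
#' random permutation (preserving that chunk's label counts), reruns the
#' full leave-one-subject-out scheme against the unpermuted test labels,
#' and records the mean accuracy.  The p-value
#' `(1 + #(null >= observed)) / (1 + n_iter)` respects the permutation
#' floor and is reproducible given `seed`.
#'
#' @param ds A `voxel_sample_set`.
#' @param observed The `loso_result` for the true labels.
#' @param n_iter Number of permutations (default 1000; below 100 refused).
#' @param seed RNG seed.
#' @param svm_cost SVM cost parameter, matching the observed analysis.
#' @return An object of class `permutation_result`: `null_accuracies`,
#'   `p`, `n_iter`, `rng_seed`, `observed_accuracy`.
#' @export
permutation_null <- function(ds, observed, n_iter = 1000L, seed = 1L,
                             svm_cost = observed$svm_cost) {
  stopifnot(inherits(ds, "voxel_sample_set"),
            inherits(observed, "loso_result"))
  if (n_iter < 100L)
    stop("n_iter < 100 gives an unusably coarse null", call. = FALSE)
  Xt <- t(cbind(ds$coords, 1))
  lab01 <- matrix(as.integer(ds$labels == "PRC"), nrow(ds$labels))
  null_acc <- .loso_perm_null_cpp(Xt, lab01, as.integer(n_iter),
                                  svm_cost, as.integer(seed))
  p <- (1 + sum(null_acc >= observed$mean_accuracy)) / (1 + n_iter)
  structure(list(null_accuracies = null_acc, p = p,
                 n_iter = as.integer(n_iter), rng_seed = as.integer(seed),
                 observed_accuracy = observed$mean_accuracy),
            class = "permutation_result")
}

#' Per-voxel classification consistency map
#'
#' The proportion of cross-validation folds in which each voxel's
#' preference was predicted correctly.
#'
#' @param res A `loso_result`.
#' @param ds The `voxel_sample_set` it was computed on.
#' @return Numeric vector in `[0, 1]`, named by voxel index.
#' @export
consistency_map <- function(res, ds) {
  stopifnot(inherits(res, "loso_result"),
            inherits(ds, "voxel_sample_set"))
  out <- rowMeans(res$predictions == ds$labels)
  names(out) <- ds$voxels
  out
}

#' Classifier-predicted EC subregion masks
#'
#' Majority vote over the folds' predictions at each voxel: voxels
#' predicted PRC-preferring in most folds form the anterior-lateral EC
#' mask, PHC-preferring voxels the posterior-medial EC mask, and exact
#' vote ties stay unassigned.  The three sets partition the ROI.
#'
#' @param res A `loso_result`.
#' @param voxels Integer voxel indices of the ROI (defaults to the sample
#'   set's voxels via `res` dimensions being row-matched).
#' @return An object of class `predicted_parcels`: list with `al_ec`,
#'   `pm_ec`, `unassigned` integer voxel vectors.
#' @export
predicted_parcels <- function(res, voxels) {
  stopifnot(inherits(res, "loso_result"))
  votes_prc <- rowSums(res$predictions == "PRC")
  nfold <- ncol(res$predictions)
  voxels <- as.integer(voxels)
  structure(list(al_ec = voxels[votes_prc > nfold / 2],
                 pm_ec = voxels[votes_prc < nfold / 2],
                 unassigned = voxels[votes_prc == nfold / 2]),
            class = "predicted_parcels")
}
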