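# Composite hallucination loss and its four components.

#' Loss weights for the composite design loss
#'
#' Defaults are the weights used for initial design trajectories:
#' `w_fape = 1.0`, `w_dist = 0.5`, `w_plddt = 0.2`, `w_ptm = 0.2`.
#' Soft-start (reseeded) trajectories disable the distogram term
#' (`w_dist = 0`).
#'
#' @param w_fape,w_dist,w_plddt,w_ptm Non-negative finite weights.
#' @param soft_start If TRUE, force `w_dist = 0`.
#' @return Named numeric vector of class `LossWeights`.
#' @export
loss_weights <- function(w_fape = 1.0, w_dist = 0.5, w_plddt = 0.2,
                         w_ptm = 0.2, soft_start = FALSE) {
  w <- c(w_fape = w_fape, w_dist = w_dist, w_plddt = w_plddt, w_ptm = w_ptm)
  if (any(!is.finite(w)) || any(w < 0)) stop("loss weights must be finite and >= 0")
  if (soft_start) w["w_dist"] <- 0
  class(w) <- "LossWeights"
  w
}

#' Frame-aligned Ca point error (simplified)
#'
#' Mean per-residue Ca L2 distance after optimal superposition of the
#' prediction onto the target, optionally clamped per residue. Unclamped it
#' equals `deviation_ca(mode = "mean")`.
#'
#' @param pred,target [Structure] objects.
#' @param corr Optional [correspondence].
#' @param clamp Per-residue distance clamp in Angstrom, or NULL (no clamp).
#' @return Loss in Angstrom.
#' @export
fape_ca_loss <- function(pred, target, corr = NULL, clamp = NULL) {
  corr <- .corr_or_identity(corr, pred, target)
  if (nrow(corr) < 3L) stop("need at least 3 corresponded pairs")
  xp <- ca_xyz(pred)[corr[, 1] + 1L, , drop = FALSE]
  xt <- ca_xyz(target)[corr[, 2] + 1L, , drop = FALSE]
  if (anyNA(xp) || anyNA(xt)) stop("missing Ca atom at a corresponded residue")
  tr <- .kabsch(xp, xt)
  d <- sqrt(rowSums((sweep(xp %*% t(tr$rotation), 2, tr$translation, `+`) - xt)^2))
  if (!is.null(clamp)) d <- pmin(d, clamp)
  mean(d)
}

#' Distogram bin edges and bin lookup
#'
#' 64 bins with 63 edges uniform from 2.3125 to 21.6875 Angstrom; bin 1 is
#' everything below the first edge, bin 64 is open-ended above the last.
#'
#' @return Numeric vector of the 63 edges.
#' @export
distogram_edges <- function() seq(2.3125, 21.6875, length.out = 63)

#' @rdname distogram_edges
#' @param d Distances (Angstrom).
#' @export
distogram_bin <- function(d) findInterval(d, distogram_edges()) + 1L

# per-residue distogram reference point: CB, or CA for glycine (and any
# residue lacking CB)
.distogram_points <- function(s) {
  cb <- atom_xyz(s, "CB")
  ca <- atom_xyz(s, "CA")
  gly <- residue_table(s)$resname == "GLY" | is.na(cb[, 1])
  cb[gly, ] <- ca[gly, ]
  list(xyz = cb, use_ca = gly)
}

#' True distogram bin matrix of a target structure
#'
#' @param target A [Structure].
#' @return Integer N x N matrix of bin indices (1..64), 0 on the diagonal.
#' @export
target_distogram_bins <- function(target) {
  p <- .distogram_points(target)
  d <- as.matrix(stats::dist(p$xyz))
  b <- matrix(distogram_bin(d), nrow(d), ncol(d))
  diag(b) <- 0L
  storage.mode(b) <- "integer"
  b
}

#' Distogram cross-entropy loss
#'
#' Mean over residue pairs (i < j) of `-log p(bin containing the true
#' distance)`, with the true distance measured between CB atoms (CA for
#' glycine) of the target.
#'
#' @param pred_bins N x N x 64 array of predicted bin probabilities; each
#'   pair's 64-vector must sum to 1 within 1e-6.
#' @param target A [Structure] with N residues.
#' @return Loss in nats.
#' @export
distogram_loss <- function(pred_bins, target) {
  n <- n_residues(target)
  dm <- dim(pred_bins)
  if (length(dm) != 3L || dm[1] != n || dm[2] != n || dm[3] != 64L)
    stop("pred_bins must be an N x N x 64 array matching the target length")
  tb <- target_distogram_bins(target)
  total <- 0; npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pv <- pred_bins[i, j, ]
      if (abs(sum(pv) - 1) > 1e-6)
        stop("probability vector for pair (", i, ",", j, ") does not sum to 1")
      total <- total - log(max(pv[tb[i, j]], 1e-300))
      npair <- npair + 1L
    }
  }
  total / npair
}

#' pLDDT confidence loss
#'
#' `1 - mean(per-residue confidence)`; confidences on the 0-100 scale are
#' rescaled to the unit interval at ingestion.
#'
#' @param per_residue_confidence Numeric vector in [0, 1] (or [0, 100]).
#' @return Loss in [0, 1].
#' @export
plddt_loss <- function(per_residue_confidence) {
  p <- per_residue_confidence
  if (max(p) > 2 && all(p >= 0) && all(p <= 100)) p <- p / 100  # 0-100 scale
  if (any(p < 0 | p > 1)) stop("pLDDT values outside [0, 1]")
  1 - mean(p)
}

#' pTM confidence loss
#'
#' @param ptm Global predicted TM-score in [0, 1].
#' @return `1 - ptm`.
#' @export
ptm_loss <- function(ptm) {
  if (length(ptm) != 1L || ptm < 0 || ptm > 1) stop("ptm must be a scalar in [0, 1]")
  1 - ptm
}

#' Weighted composite loss
#'
#' `total = w_fape * l_fape + w_dist * l_dist + w_plddt * l_plddt +
#' w_ptm * l_ptm`.
#'
#' @param l_fape,l_dist,l_plddt,l_ptm Component values.
#' @param w [loss_weights].
#' @return Named list of class `LossBreakdown` with the components and `total`.
#' @export
composite_loss <- function(l_fape, l_dist, l_plddt, l_ptm, w = loss_weights()) {
  comp <- c(l_fape, l_dist, l_plddt, l_ptm)
  if (any(!is.finite(comp))) stop("non-finite loss component")
  if (any(w < 0)) stop("negative loss weight")
  out <- list(l_fape = l_fape, l_dist = l_dist, l_plddt = l_plddt,
              l_ptm = l_ptm,
              total = sum(as.numeric(w) * comp))
  class(out) <- "LossBreakdown"
  out
}

#' @export
print.LossBreakdown <- function(x, ...) {
  cat(sprintf("loss total %.4f (fape %.4f, dist %.4f, plddt %.4f, ptm %.4f)\n",
              x$total, x$l_fape, x$l_dist, x$l_plddt, x$l_ptm))
  invisible(x)
}
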