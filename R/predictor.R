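# Structure-predictor contract and the deterministic toy folder.
#
# The toy folder stands in the structure-predictor role for desk-scale runs:
# it maps per-position amino-acid probabilities to secondary-structure class
# propensities through a fixed 20 x 3 table, builds ideal-geometry backbone
# coordinates from the propensity-blended class torsions, and reports
# confidence as the sharpness of the class distribution. Five ensemble
# members differ by fixed +/-2% perturbations of the propensity table.
# Adapters for real neural predictors implement the same contract (see
# `predictor_contract()`); they are interface stubs here.

.TOY_BETA <- 8        # confidence sharpness
.TOY_BETA_BLEND <- 16 # torsion blend sharpness (dominant class ~ ideal geometry)
.TOY_SIGMA <- 0.75    # toy distogram smoothing (A)
.TOY_FD_H <- 1e-4     # finite-difference step

#' Position-specific scoring matrix (PSSM)
#'
#' N x 20 logit matrix over the alphabet `ACDEFGHIKLMNPQRSTVWY`. The cysteine
#' column is masked to -1e9 by default so decoded sequences never contain C.
#'
#' @param logits N x 20 numeric matrix.
#' @param mask_cys Mask the C column.
#' @return Matrix of class `PSSM`.
#' @export
pssm <- function(logits, mask_cys = TRUE) {
  logits <- as.matrix(logits)
  if (ncol(logits) != 20L) stop("PSSM must have 20 columns")
  if (any(!is.finite(logits) & logits != -1e9)) {
    if (any(is.na(logits)) || any(is.nan(logits)) || any(logits == Inf))
      stop("non-finite PSSM logits")
  }
  colnames(logits) <- aa_alphabet()
  if (mask_cys) logits[, "C"] <- -1e9
  class(logits) <- c("PSSM", class(logits))
  logits
}

#' One-hot PSSM from a sequence
#'
#' @param seq Sequence string.
#' @param scale Logit value on the chosen letter (0 elsewhere); the default
#'   +4 gives a near-deterministic softmax without saturating gradients.
#' @param mask_cys Mask the C column.
#' @return A [pssm].
#' @export
pssm_from_sequence <- function(seq, scale = 4, mask_cys = TRUE) {
  idx <- seq_to_int(validate_sequence(seq))
  m <- matrix(0, length(idx), 20)
  m[cbind(seq_along(idx), idx)] <- scale
  pssm(m, mask_cys = mask_cys)
}

# row-wise softmax
.softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Decode a PSSM into probabilities and a sequence
#'
#' Row-wise softmax followed by argmax; the cysteine column is masked before
#' the softmax so C is never emitted; ties break to the lowest alphabet index.
#'
#' @param p A [pssm] or plain N x 20 logit matrix.
#' @return List with `probabilities` (rows sum to 1) and `sequence`.
#' @export
pssm_decode <- function(p) {
  p <- pssm(unclass(p))
  q <- .softmax_rows(unclass(p))
  idx <- apply(q, 1, which.max)  # which.max takes the first (lowest) index on ties
  list(probabilities = q, sequence = int_to_seq(idx))
}

#' Predictor configuration
#'
#' @param n_recycles Refinement recycles (0 in design, 3 at reprediction).
#' @param ensemble_size Number of ensemble members (1..5).
#' @param single_sequence Single-sequence mode flag (informational for
#'   external adapters; the toy folder is always single-sequence).
#' @param context Optional second [Structure] held fixed during prediction
#'   (e.g. a binder present during design); passed through unchanged.
#' @return List of class `PredictorConfig`.
#' @export
predictor_config <- function(n_recycles = 0L, ensemble_size = 5L,
                             single_sequence = TRUE, context = NULL) {
  if (!n_recycles %in% 0:8) stop("n_recycles must be in 0..8")
  if (!ensemble_size %in% 1:5) stop("ensemble_size must be in 1..5")
  structure(list(n_recycles = as.integer(n_recycles),
                 ensemble_size = as.integer(ensemble_size),
                 single_sequence = isTRUE(single_sequence),
                 context = context),
            class = "PredictorConfig")
}

#' Toy folder class propensity table
#'
#' Fixed 20 x 3 table of secondary-structure class propensities (columns H,
#' E, L; rows in alphabet order). Alanine is maximal for helix, valine for
#' strand, glycine for loop; the remaining residues carry plausible
#' helix/strand/loop preferences. Rows sum to 1.
#'
#' @param member Ensemble member id in 1..5; members 2..5 apply a fixed
#'   +/-2% column perturbation and renormalize.
#' @return 20 x 3 numeric matrix.
#' @export
toy_propensity_table <- function(member = 1L) {
  P <- rbind(
    A = c(.80, .10, .10), C = c(.30, .50, .20), D = c(.30, .15, .55),
    E = c(.70, .10, .20), F = c(.40, .45, .15), G = c(.10, .10, .80),
    H = c(.50, .25, .25), I = c(.25, .65, .10), K = c(.60, .15, .25),
    L = c(.65, .20, .15), M = c(.65, .15, .20), N = c(.25, .20, .55),
    P = c(.15, .10, .75), Q = c(.60, .15, .25), R = c(.60, .15, .25),
    S = c(.30, .25, .45), T = c(.25, .55, .20), V = c(.10, .80, .10),
    W = c(.40, .45, .15), Y = c(.25, .60, .15))
  colnames(P) <- c("H", "E", "L")
  pert <- list(c(0, 0, 0), c(1, -1, 0), c(-1, 1, 0), c(0, 1, -1), c(0, -1, 1))
  if (!member %in% 1:5) stop("member must be in 1..5")
  P <- P * rep(1 + 0.02 * pert[[member]], each = 20)
  P / rowSums(P)
}

# one recycle sharpens the class propensities (confidence grows, labels fixed)
.toy_recycle <- function(S, n_recycles) {
  for (r in seq_len(n_recycles)) {
    S <- S^1.3
    S <- S / rowSums(S)
  }
  S
}

# probabilities from a PSSM or a plain sequence (exact one-hot)
.input_probs <- function(input) {
  if (inherits(input, "PSSM")) return(pssm_decode(input)$probabilities)
  if (is.character(input) && length(input) == 1L) {
    idx <- seq_to_int(validate_sequence(input))
    q <- matrix(0, length(idx), 20)
    q[cbind(seq_along(idx), idx)] <- 1
    colnames(q) <- aa_alphabet()
    return(q)
  }
  if (is.matrix(input)) return(pssm_decode(pssm(input))$probabilities)
  stop("input must be a PSSM, logit matrix, or sequence string")
}

#' Deterministic toy structure predictor
#'
#' @param compute_distogram Attach the full N x N x 64 distogram to each
#'   prediction (costly; off by default).
#' @return Object of class `c("toy_predictor", "predictor")`.
#' @export
toy_predictor <- function(compute_distogram = FALSE) {
  structure(list(compute_distogram = isTRUE(compute_distogram)),
            class = c("toy_predictor", "predictor"))
}

#' Predict structures for a sequence or PSSM
#'
#' Generic predictor contract: deterministic given (input, config, member).
#' Returns one `PredictionResult` per ensemble member, each with `structure`
#' (backbone + CB + pseudo side-chain), `plddt` (per residue, [0,1]), `ptm`,
#' `labels` (H/E/L string), `model_id`, and optionally `distogram`.
#'
#' @param predictor A predictor object (e.g. [toy_predictor]).
#' @param input A [pssm], logit matrix, or sequence string (length N >= 10).
#' @param cfg A [predictor_config].
#' @return List of `PredictionResult` objects, length `cfg$ensemble_size`.
#' @export
predict_structure <- function(predictor, input, cfg = predictor_config()) {
  UseMethod("predict_structure")
}

#' @export
predict_structure.toy_predictor <- function(predictor, input,
                                            cfg = predictor_config()) {
  stopifnot(inherits(cfg, "PredictorConfig"))
  q <- .input_probs(input)
  n <- nrow(q)
  if (n < 10L) stop("toy predictor requires N >= 10 residues")
  seq_dec <- int_to_seq(apply(q, 1, which.max))
  tab <- class_torsion_tables(n)
  lapply(seq_len(cfg$ensemble_size), function(m) {
    S <- .toy_recycle(q %*% toy_propensity_table(m), cfg$n_recycles)
    labels <- c("H", "E", "L")[apply(S, 1, which.max)]
    # torsion blend weights: softmax-sharpened propensities, so a dominant
    # class reproduces its ideal torsions
    B <- .softmax_rows(.TOY_BETA_BLEND * S)
    phi <- rowSums(B * tab$phi); psi <- rowSums(B * tab$psi)
    bb <- cpp_build_chain(phi, psi)
    str <- build_structure_from_backbone(bb$n, bb$ca, bb$c, bb$o, seq_dec)
    if (!is.null(cfg$context)) {
      ctx <- cfg$context$atoms
      ctx$chain <- "X"
      str <- Structure(rbind(str$atoms, ctx))
    }
    plddt <- apply(S, 1, function(si) max(.softmax_rows(matrix(.TOY_BETA * si, 1))))
    res <- list(structure = str, plddt = as.numeric(plddt),
                ptm = mean(plddt), labels = paste(labels, collapse = ""),
                model_id = m, sequence = seq_dec)
    if (predictor$compute_distogram) res$distogram <- .toy_distogram(str)
    class(res) <- "PredictionResult"
    res
  })
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf("PredictionResult (model %d): %d residues, mean pLDDT %.3f, pTM %.3f\n",
              x$model_id, length(x$plddt), mean(x$plddt), x$ptm))
  invisible(x)
}

# full N x N x 64 smoothed distogram from a predicted structure
.toy_distogram <- function(s) {
  p <- .distogram_points(s)
  n <- nrow(p$xyz)
  d <- as.matrix(stats::dist(p$xyz))
  edges <- distogram_edges()
  lo <- c(-Inf, edges); hi <- c(edges, Inf)
  arr <- array(0, c(n, n, 64))
  for (k in 1:64) {
    arr[, , k] <- stats::pnorm((hi[k] - d) / .TOY_SIGMA) -
      stats::pnorm((lo[k] - d) / .TOY_SIGMA)
  }
  arr
}

# precomputed target quantities shared by loss and gradient evaluations
.toy_target_cache <- function(target) {
  ca <- ca_xyz(target)
  if (anyNA(ca)) stop("target is missing Ca atoms")
  rt <- residue_table(target)
  tab <- class_torsion_tables(nrow(ca))
  list(ca = ca,
       true_bin = target_distogram_bins(target),
       use_ca = residue_table(target)$resname == "GLY",
       phi = unname(tab$phi), psi = unname(tab$psi),
       n = nrow(ca))
}

# composite loss breakdown of one toy member for probabilities q
.toy_eval <- function(q, cache, w, member = 1L, n_recycles = 0L,
                      clamp = NULL) {
  S <- .toy_recycle(q %*% toy_propensity_table(member), n_recycles)
  v <- cpp_toy_loss(S, cache$phi, cache$psi, cache$ca, cache$true_bin,
                    cache$use_ca, as.numeric(w), .TOY_BETA, .TOY_BETA_BLEND,
                    .TOY_SIGMA, if (is.null(clamp)) -1 else clamp)
  composite_loss(v[1], v[2], v[3], v[4], w)
}

#' Ensemble loss gradient of the toy folder
#'
#' Gradient of the weighted composite loss with respect to the PSSM logits,
#' computed by central finite differences (step 1e-4) on the structural
#' channel for each ensemble member and averaged over members.
#'
#' @param p A [pssm].
#' @param target Target [Structure], same length as the PSSM.
#' @param w [loss_weights].
#' @param cfg [predictor_config].
#' @param cache Optional precomputed target cache (internal reuse).
#' @return N x 20 numeric gradient matrix.
#' @export
ensemble_loss_gradient <- function(p, target, w = loss_weights(),
                                   cfg = predictor_config(), cache = NULL) {
  if (is.null(cache)) cache <- .toy_target_cache(target)
  q <- pssm_decode(p)$probabilities
  if (nrow(q) != cache$n) stop("PSSM length != target length")
  g <- matrix(0, nrow(q), 20)
  for (m in seq_len(cfg$ensemble_size)) {
    gm <- cpp_member_grad(q, toy_propensity_table(m), cache$phi, cache$psi,
                          cache$ca, cache$true_bin, cache$use_ca,
                          as.numeric(w), .TOY_BETA, .TOY_BETA_BLEND,
                          .TOY_SIGMA, -1, .TOY_FD_H)
    g <- g + gm
  }
  g <- g / cfg$ensemble_size
  if (any(!is.finite(g))) stop("non-finite gradient")
  colnames(g) <- aa_alphabet()
  g
}

# naive reference: central finite differences directly on each logit entry
# (independent oracle for the fast propensity-level path; tests only)
.toy_member_grad_naive <- function(p, target, w, member = 1L, h = 1e-5) {
  cache <- .toy_target_cache(target)
  logits <- unclass(p)
  g <- matrix(0, nrow(logits), 20)
  evalq_ <- function(lg) {
    q <- .softmax_rows(lg)
    .toy_eval(q, cache, w, member)$total
  }
  for (i in seq_len(nrow(logits))) {
    for (a in seq_len(20)) {
      if (logits[i, a] <= -1e8) next
      lp <- logits; lp[i, a] <- lp[i, a] + h
      lm <- logits; lm[i, a] <- lm[i, a] - h
      g[i, a] <- (evalq_(lp) - evalq_(lm)) / (2 * h)
    }
  }
  g
}

#' Predictor adapter contract
#'
#' Shape contract for plugging real structure predictors into the pipeline,
#' documented as a JSON-serializable schema. External adapters (e.g. for a
#' neural predictor) must accept a PSSM or sequence plus a
#' [predictor_config] and return, per ensemble member, the fields listed.
#'
#' @return Nested list describing the contract (serialize with
#'   `jsonlite::toJSON`).
#' @export
predictor_contract <- function() {
  list(
    input = list(
      pssm = "N x 20 real logits over alphabet ACDEFGHIKLMNPQRSTVWY; masked letters are -1e9",
      sequence = "string over the 20-letter alphabet",
      config = list(n_recycles = "integer 0..8", ensemble_size = "integer 1..5",
                    single_sequence = "logical", context = "optional fixed Structure")
    ),
    output_per_member = list(
      structure = "predicted coordinates (backbone + CB)",
      plddt = "per-residue confidence in [0,1], length N",
      ptm = "global confidence in [0,1]",
      distogram = "optional N x N x 64 bin probabilities, rows normalized within 1e-6",
      model_id = "integer 1..5"
    ),
    determinism = "identical (input, config, member) must give identical output"
  )
}
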