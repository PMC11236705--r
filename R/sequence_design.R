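# Inverse-folding stage: pluggable sampler contract with solubility biasing,
# backbone noise, fixed functional positions, and mock samplers.

#' Options for inverse-folding sequence sampling
#'
#' @param n_sequences Sequences to draw per backbone (pipeline default: 2).
#' @param bias 20-vector of logit offsets (see [build_sampling_bias]).
#' @param fixed_positions Named character vector: names are 0-based residue
#'   indices, values the required letters (e.g. `c("0" = "M")`).
#' @param mask_cys Never emit cysteine (default TRUE).
#' @param backbone_noise_sigma Gaussian coordinate noise (Angstrom) applied
#'   to the backbone before sampling (0 = none, the pipeline default).
#' @param rng_seed Integer seed.
#' @return List of class `SamplerOptions`.
#' @export
sampler_options <- function(n_sequences = 2L, bias = numeric(20),
                            fixed_positions = character(0), mask_cys = TRUE,
                            backbone_noise_sigma = 0, rng_seed = 1L) {
  if (length(bias) != 20L || any(!is.finite(bias)))
    stop("bias must be a finite 20-vector")
  if (backbone_noise_sigma < 0) stop("backbone_noise_sigma must be >= 0")
  if (length(fixed_positions)) {
    if (is.null(names(fixed_positions))) stop("fixed_positions must be named by 0-based index")
    if (any(!fixed_positions %in% aa_alphabet()))
      stop("fixed_positions letters must be canonical amino acids")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 bias = stats::setNames(as.numeric(bias), aa_alphabet()),
                 fixed_positions = fixed_positions,
                 mask_cys = isTRUE(mask_cys),
                 backbone_noise_sigma = backbone_noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "SamplerOptions")
}

#' Add Gaussian noise to backbone coordinates
#'
#' I.i.d. zero-mean Gaussian displacement (standard deviation `sigma` per
#' coordinate axis) added to every atom. `sigma = 0` returns the structure
#' unchanged; deterministic per seed.
#'
#' @param s A [Structure].
#' @param sigma Noise standard deviation (Angstrom).
#' @param rng_seed Integer seed.
#' @return A [Structure].
#' @export
add_backbone_noise <- function(s, sigma, rng_seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(s)
  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng))
  set.seed(as.integer(rng_seed))
  n_atoms <- nrow(s$atoms)
  noise <- matrix(stats::rnorm(3L * n_atoms, 0, sigma), n_atoms, 3)
  transform_coords(s, function(xyz) xyz + noise)
}

#' Solubility sampling bias vector
#'
#' `+polar_bonus` on the polar residues D,E,H,K,N,Q,R,S,T,Y and
#' `-alanine_penalty` on alanine; zero elsewhere. Added to the sampler's
#' per-position logits before sampling.
#'
#' @param polar_bonus,alanine_penalty Finite reals.
#' @return Named 20-vector of logit offsets.
#' @export
build_sampling_bias <- function(polar_bonus, alanine_penalty) {
  if (!is.finite(polar_bonus) || !is.finite(alanine_penalty))
    stop("bias parameters must be finite")
  b <- stats::setNames(numeric(20), aa_alphabet())
  b[aa_polar()] <- polar_bonus
  b["A"] <- b["A"] - alanine_penalty
  b
}

#' Mock inverse-folding samplers
#'
#' Inverse-folding samplers implement a single contract: given a backbone
#' [Structure], return an N x 20 matrix of per-position letter logits.
#' `mock_uniform_sampler()` is backbone-blind (all-zero logits);
#' `mock_burial_sampler()` conditions on the backbone the way a real
#' inverse-folding network does, in two coarse ways: letters compatible with
#' the local secondary structure get a propensity-proportional bonus, and
#' buried positions get a hydrophobic bonus while exposed positions get a
#' polar bonus, proportional to burial computed from per-residue SASA —
#' enough to exercise surface-solubilization behavior end-to-end without
#' network weights.
#'
#' @param strength Logit scale of the burial-aware preferences.
#' @param sasa_ref SASA (Angstrom^2) treated as fully exposed.
#' @param ss_weight Logit scale of the secondary-structure compatibility term.
#' @return Function `(backbone) -> N x 20 logits` of class `if_sampler`.
#' @name mock_samplers
#' @export
mock_uniform_sampler <- function() {
  f <- function(backbone) {
    n <- n_residues(backbone)
    m <- matrix(0, n, 20)
    colnames(m) <- aa_alphabet()
    m
  }
  class(f) <- c("if_sampler", class(f))
  f
}

#' @rdname mock_samplers
#' @export
mock_burial_sampler <- function(strength = 3, sasa_ref = 80, ss_weight = 8) {
  f <- function(backbone) {
    sasa <- sasa_per_residue(backbone)
    burial <- 1 - pmin(as.numeric(sasa) / sasa_ref, 1)
    n <- length(burial)
    cls <- torsion_class(backbone)  # local-geometry class, one per residue
    P <- toy_propensity_table(1L)
    letter_class <- colnames(P)[apply(P, 1, which.max)]
    # +ss_weight for letters whose preferred class matches the local backbone
    m <- ss_weight * outer(cls, letter_class, `==`)
    colnames(m) <- aa_alphabet()
    colnames(m) <- aa_alphabet()
    hydro <- setdiff(aa_apolar(), c("G", "P"))  # structural G/P not rewarded
    m[, hydro] <- m[, hydro] + strength * burial
    m[, aa_polar()] <- m[, aa_polar()] + strength * (1 - burial)
    m
  }
  class(f) <- c("if_sampler", class(f))
  f
}

#' Sample sequences for a backbone
#'
#' Applies backbone noise (if requested), queries the sampler for
#' per-position logits, adds the solubility bias, masks cysteine, forces
#' fixed positions to their required letters, and draws
#' `opts$n_sequences` sequences by per-position categorical sampling.
#' Deterministic per `opts$rng_seed`.
#'
#' @param backbone A [Structure].
#' @param sampler An inverse-folding sampler (see [mock_samplers]).
#' @param opts [sampler_options].
#' @return Character vector of sequences (length `opts$n_sequences`).
#' @export
sample_sequences <- function(backbone, sampler = mock_uniform_sampler(),
                             opts = sampler_options()) {
  stopifnot(inherits(opts, "SamplerOptions"))
  if (opts$backbone_noise_sigma > 0)
    backbone <- add_backbone_noise(backbone, opts$backbone_noise_sigma,
                                   rng_seed = opts$rng_seed + 1L)
  logits <- sampler(backbone)
  n <- n_residues(backbone)
  if (!is.matrix(logits) || nrow(logits) != n || ncol(logits) != 20L)
    stop("sampler failure: expected an N x 20 logit matrix")
  logits <- sweep(logits, 2, opts$bias, `+`)
  if (opts$mask_cys) logits[, match("C", aa_alphabet())] <- -1e9
  fixed_idx <- integer(0)
  if (length(opts$fixed_positions)) {
    fixed_idx <- as.integer(names(opts$fixed_positions))
    if (any(fixed_idx < 0L | fixed_idx >= n))
      stop("fixed position index out of range [0, ", n - 1L, "]")
  }
  probs <- .softmax_rows(logits)
  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng))
  set.seed(opts$rng_seed)
  out <- character(opts$n_sequences)
  for (k in seq_len(opts$n_sequences)) {
    idx <- vapply(seq_len(n), function(i)
      sample.int(20L, 1L, prob = probs[i, ]), integer(1))
    chars <- aa_alphabet()[idx]
    if (length(fixed_idx)) chars[fixed_idx + 1L] <- unname(opts$fixed_positions)
    out[k] <- paste(chars, collapse = "")
  }
  out
}

#' Read a fixed-position selection file
#'
#' TSV with columns `chain`, `index` (0-based) and `letter`; returns the
#' named-vector form [sampler_options] expects for a single chain.
#'
#' @param path TSV file path.
#' @param chain Chain to select (default: all rows).
#' @return Named character vector (names = 0-based indices).
#' @export
read_fixed_positions <- function(path, chain = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("chain", "index", "letter")
  if (!all(req %in% names(df)))
    stop("fixed-position file needs columns: ", paste(req, collapse = ", "))
  if (!is.null(chain)) df <- df[df$chain == chain, , drop = FALSE]
  if (any(!df$letter %in% aa_alphabet()))
    stop("fixed-position file contains a non-canonical letter")
  stats::setNames(df$letter, as.character(df$index))
}

#' Fixed-position presets for functional (claudin-style) design
#'
#' Two strategies for solubilizing a fold while preserving a functional
#' region: `"transmembrane-surface"` redesigns only the solvent-facing
#' membrane-spanning surface (everything else fixed, roughly 40% designable)
#' and `"transmembrane-all"` redesigns the whole membrane-spanning segment
#' including its core (roughly 60% designable). Membrane-spanning positions
#' are taken from a logical mask (e.g. helix residues of the fixture's truth
#' labels); surface positions come from [classify_layers].
#'
#' @param s A [Structure] carrying the native sequence.
#' @param tm_mask Logical vector, TRUE at membrane-spanning positions.
#' @param preset `"transmembrane-surface"` or `"transmembrane-all"`.
#' @return Named character vector of fixed positions for [sampler_options].
#' @export
fixed_positions_preset <- function(s, tm_mask,
                                   preset = c("transmembrane-surface",
                                              "transmembrane-all")) {
  preset <- match.arg(preset)
  n <- n_residues(s)
  if (length(tm_mask) != n) stop("tm_mask length != residue count")
  seq <- extract_sequence(s, permissive = TRUE)
  designable <- if (preset == "transmembrane-all") tm_mask else {
    layers <- classify_layers(s)
    tm_mask & layers == "surface"
  }
  fixed <- which(!designable) - 1L
  stats::setNames(strsplit(seq, "")[[1]][fixed + 1L], as.character(fixed))
}
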