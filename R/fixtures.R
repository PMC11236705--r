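# Synthetic structure/sequence fixtures: deterministic, download-free inputs
# for every pipeline stage, with ground-truth secondary structure and layers.

#' Fixture specification
#'
#' @param kind One of `helix`, `strand`, `helix_bundle`, `beta_hairpin`,
#'   `barrel_like`, `tim_like`, `membrane_like_bundle`.
#' @param n_res Total residue count (>= 5; kinds with fixed architecture
#'   round to the nearest feasible layout).
#' @param seed Integer seed (used by any stochastic choices; the geometry
#'   itself is deterministic).
#' @param loop_len Connector length between secondary-structure elements.
#' @param radius Offset (Angstrom) of the flanking helices from the central
#'   sheet (`tim_like` only; default 9).
#' @return List of class `FixtureSpec`.
#' @export
fixture_spec <- function(kind, n_res, seed = 1L, loop_len = 4L, radius = NULL) {
  kinds <- c("helix", "strand", "helix_bundle", "beta_hairpin",
             "barrel_like", "tim_like", "membrane_like_bundle")
  if (!kind %in% kinds) stop("unknown fixture kind: ", kind)
  if (n_res < 5L) stop("n_res must be >= 5")
  structure(list(kind = kind, n_res = as.integer(n_res),
                 seed = as.integer(seed), loop_len = as.integer(loop_len),
                 radius = radius),
            class = "FixtureSpec")
}

# split n_res into k elements of length >= min_el joined by loops of loop_len
.layout <- function(n_res, k, loop_len, min_el = 5L) {
  body <- n_res - (k - 1L) * loop_len
  if (body < k * min_el)
    stop("n_res too small for ", k, " elements with ", loop_len, "-residue loops")
  lens <- rep(body %/% k, k)
  extra <- body %% k
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  lens
}

.ss_string <- function(el_lens, el_lab, loop_len) {
  parts <- character(0)
  for (i in seq_along(el_lens)) {
    parts <- c(parts, strrep(el_lab[i], el_lens[i]))
    if (i < length(el_lens)) parts <- c(parts, strrep("L", loop_len))
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic fixture structure
#'
#' Ideal-geometry backbone with known secondary structure; helical kinds are
#' built in torsion space (helix segments joined by a fixed turn pattern, so
#' the toy predictor can reproduce them exactly), sheet-containing kinds are
#' assembled from rigidly placed ideal strands with hydrogen-bond registry.
#' Buried/exposed layer labels are derived from the constructed geometry.
#'
#' @param spec A [fixture_spec].
#' @return List of class `Fixture` with `structure` ([Structure]), `ss`
#'   (truth string over H/E/L), `layers` (core/boundary/surface), `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  out <- switch(spec$kind,
    helix = .fx_torsion(strrep("H", spec$n_res)),
    strand = .fx_torsion(strrep("E", spec$n_res)),
    helix_bundle = .fx_bundle(spec),
    membrane_like_bundle = .fx_membrane_bundle(spec),
    beta_hairpin = .fx_hairpin(spec),
    barrel_like = .fx_barrel(spec, with_helices = FALSE),
    tim_like = .fx_barrel(spec, with_helices = TRUE)
  )
  out$layers <- classify_layers(out$structure)
  out$spec <- spec
  class(out) <- "Fixture"
  out
}

#' @export
print.Fixture <- function(x, ...) {
  cat("Fixture:", x$spec$kind, "-", n_residues(x$structure), "residues\n")
  cat("  ss:    ", x$ss, "\n")
  cat("  layers:", paste(substr(x$layers, 1, 1), collapse = ""), "\n")
  invisible(x)
}

.fx_torsion <- function(ss, seq = NULL) {
  list(structure = build_structure_from_ss(ss, seq), ss = ss)
}

.fx_bundle <- function(spec, n_helices = NULL) {
  if (is.null(n_helices)) n_helices <- if (spec$n_res >= 52L) 4L else 3L
  lens <- .layout(spec$n_res, n_helices, spec$loop_len, min_el = 7L)
  ss <- .ss_string(lens, rep("H", n_helices), spec$loop_len)
  .fx_torsion(ss)
}

.fx_membrane_bundle <- function(spec) {
  fx <- .fx_bundle(spec, n_helices = 4L)
  s <- fx$structure
  # membrane-protein-like sequence: hydrophobic surface, hydrophobic core
  lay <- classify_layers(s)
  lab <- strsplit(fx$ss, "")[[1]]
  chars <- ifelse(lab == "L", "G",
                  ifelse(lay == "surface",
                         rep_len(c("L", "F", "I", "M"), length(lab)),
                         rep_len(c("A", "L"), length(lab))))
  seq <- paste(chars, collapse = "")
  list(structure = set_sequence(s, seq), ss = fx$ss)
}

# ---- assembled sheet fixtures ----------------------------------------------

# ideal extended strand backbone of k residues, centered, running along +x
.strand_template <- function(k) {
  w <- ss_to_weights(strrep("E", k))
  tor <- torsions_from_weights(w)
  bb <- build_backbone(tor$phi, tor$psi)
  ctr <- colMeans(bb$ca)
  # principal axis -> x
  sv <- svd(sweep(bb$ca, 2, ctr))
  R <- sv$v
  if (det(R) < 0) R[, 3] <- -R[, 3]
  lapply(bb, function(m) sweep(m, 2, ctr) %*% R)
}

.rigid <- function(bb, R, t) lapply(bb, function(m) sweep(m %*% t(R), 2, t, `+`))

.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
.rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# concatenate backbone segments, bridging with loop_len interpolated residues
.assemble <- function(segments, labels, loop_len) {
  bbs <- list(); labs <- character(0)
  for (i in seq_along(segments)) {
    bbs[[length(bbs) + 1L]] <- segments[[i]]
    labs <- c(labs, strsplit(labels[i], "")[[1]])
    if (i < length(segments) && loop_len > 0L) {
      a <- segments[[i]]; b <- segments[[i + 1L]]
      na <- nrow(a$ca)
      conn <- list(n = NULL, ca = NULL, c = NULL, o = NULL)
      for (t in seq_len(loop_len)) {
        f <- t / (loop_len + 1)
        shift_a <- lapply(a, function(m) m[na, , drop = FALSE])
        shift_b <- lapply(b, function(m) m[1, , drop = FALSE])
        for (nm in names(conn)) {
          conn[[nm]] <- rbind(conn[[nm]],
                              (1 - f) * shift_a[[nm]] + f * shift_b[[nm]])
        }
      }
      bbs[[length(bbs) + 1L]] <- conn
      labs <- c(labs, rep("L", loop_len))
    }
  }
  bb <- list(n = do.call(rbind, lapply(bbs, `[[`, "n")),
             ca = do.call(rbind, lapply(bbs, `[[`, "ca")),
             c = do.call(rbind, lapply(bbs, `[[`, "c")),
             o = do.call(rbind, lapply(bbs, `[[`, "o")))
  list(bb = bb, ss = paste(labs, collapse = ""))
}

# antiparallel partner placement: near-180 rotation about the sheet normal
# composed with a flip about the strand axis, plus a cross-sheet offset;
# tuned once so the backbone H-bond registry seen by the DSSP-style assigner
# actually forms on idealized strands
.sheet_partner_rot <- function() .rot_z(175) %*% .rot_x(180)
.SHEET_SHIFT <- c(-0.75, 3.4, 0)

.fx_hairpin <- function(spec) {
  loop_len <- spec$loop_len
  k <- (spec$n_res - loop_len) %/% 2L
  if (k < 3L) stop("n_res too small for a hairpin")
  a <- .strand_template(k)
  b <- .rigid(a, .sheet_partner_rot(), .SHEET_SHIFT)
  # reverse residue order of the second strand so the chain runs back
  b <- lapply(b, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  asm <- .assemble(list(a, b), c(strrep("E", k), strrep("E", k)), loop_len)
  seq <- init_sequence_from_ss(asm$ss)
  list(structure = build_structure_from_backbone(asm$bb$n, asm$bb$ca,
                                                 asm$bb$c, asm$bb$o, seq),
       ss = asm$ss)
}

# barrel_like: eight strands walking once around a core as an up-down
# meander (adjacent strands carry H-bond registry via the calibrated partner
# transform). tim_like: the same eight-strand sheet with a helix between
# consecutive strands, flanking the sheet on alternating faces — the
# strand-helix alternation that gives TIM-class folds their long-range
# contacts. `radius` sets the helix offset from the sheet (default 9 A).
.fx_barrel <- function(spec, with_helices = FALSE) {
  n_el <- 8L
  loop_len <- min(spec$loop_len, 3L)
  if (with_helices) {
    # 8 strands + 7 flanking helices; strand length fixed at 6, helices take
    # the remaining budget (layouts round to the nearest feasible size)
    strand_len <- 6L
    helix_len <- max(5L, round((spec$n_res - 8L * strand_len -
                                  14L * loop_len) / 7))
  } else {
    lens <- .layout(spec$n_res, n_el, loop_len, min_el = 5L)
    strand_len <- lens[1]
  }
  helix_offset <- if (!is.null(spec$radius)) spec$radius else 9
  tmpl <- .strand_template(strand_len)
  R_p <- .sheet_partner_rot(); t_p <- .SHEET_SHIFT
  poses <- vector("list", n_el)
  R_cum <- diag(3); t_cum <- c(0, 0, 0)
  for (i in seq_len(n_el)) {
    poses[[i]] <- list(R = R_cum, t = t_cum)
    t_cum <- as.numeric(R_p %*% t_cum) + t_p
    R_cum <- R_p %*% R_cum
  }
  segs <- list(); labs <- character(0)
  for (i in seq_len(n_el)) {
    st <- .rigid(tmpl, poses[[i]]$R, poses[[i]]$t)
    if (i %% 2L == 0L)  # chain walks back along even strands
      st <- lapply(st, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
    segs[[length(segs) + 1L]] <- st
    labs <- c(labs, strrep("E", strand_len))
    if (with_helices && i < n_el) {
      hx_ss <- strrep("H", helix_len)
      tor <- torsions_from_weights(ss_to_weights(hx_ss))
      hx <- build_backbone(tor$phi, tor$psi)
      ctr <- colMeans(hx$ca)
      hx <- lapply(hx, function(m) sweep(m, 2, ctr))
      # align the helix axis with the strands (x), park it beside the sheet
      sv <- svd(sweep(hx$ca, 2, colMeans(hx$ca)))
      Rh <- sv$v; if (det(Rh) < 0) Rh[, 3] <- -Rh[, 3]
      hx <- lapply(hx, function(m) m %*% Rh)
      mid <- (colMeans(segs[[length(segs)]]$ca) +
                as.numeric(poses[[i + 1L]]$t)) / 2
      off <- c(0, 0, helix_offset * if (i %% 2L == 0L) -1 else 1)
      hx <- .rigid(hx, diag(3), mid + off)
      segs[[length(segs) + 1L]] <- hx
      labs <- c(labs, hx_ss)
    }
  }
  asm <- .assemble(segs, labs, loop_len)
  seq <- init_sequence_from_ss(asm$ss)
  list(structure = build_structure_from_backbone(asm$bb$n, asm$bb$ca,
                                                 asm$bb$c, asm$bb$o, seq),
       ss = asm$ss)
}

#' Generate a fixture and a noise-perturbed copy
#'
#' For metric calibration: returns the fixture structure and a copy with
#' i.i.d. Gaussian coordinate noise of the stated magnitude.
#'
#' @param spec A [fixture_spec].
#' @param perturbation Per-axis Gaussian displacement sd (Angstrom, >= 0).
#' @return List of two [Structure] objects (`original`, `perturbed`).
#' @export
generate_target_pair <- function(spec, perturbation) {
  if (perturbation < 0) stop("perturbation must be >= 0")
  fx <- generate_fixture(spec)
  list(original = fx$structure,
       perturbed = add_backbone_noise(fx$structure, perturbation,
                                      rng_seed = spec$seed))
}

#' Export a fixture as PDB plus a truth TSV
#'
#' @param fx A [generate_fixture] result.
#' @param pdb_path,tsv_path Output paths.
#' @return Invisibly, `pdb_path`.
#' @export
write_fixture <- function(fx, pdb_path, tsv_path) {
  write_structure(fx$structure, pdb_path, format = "pdb")
  rt <- residue_table(fx$structure)
  df <- data.frame(chain = rt$chain, index = rt$index, resname = rt$resname,
                   ss = strsplit(fx$ss, "")[[1]], layer = fx$layers)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pdb_path)
}
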