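# Superposition, deviation metrics, TM-score, SASA and secondary structure.

#' Residue correspondence between two structures
#'
#' @param index_a,index_b Equal-length integer vectors of 0-based residue
#'   indices (global residue order, chains concatenated).
#' @return Object of class `Correspondence` (2-column integer matrix).
#' @export
correspondence <- function(index_a, index_b) {
  index_a <- as.integer(index_a); index_b <- as.integer(index_b)
  if (length(index_a) != length(index_b)) stop("index vectors differ in length")
  if (anyDuplicated(index_a) || anyDuplicated(index_b))
    stop("duplicate indices in correspondence")
  if (any(index_a < 0L) || any(index_b < 0L)) stop("indices must be 0-based, >= 0")
  m <- cbind(a = index_a, b = index_b)
  class(m) <- c("Correspondence", class(m))
  m
}

#' @rdname correspondence
#' @param n Number of residues.
#' @export
identity_correspondence <- function(n) correspondence(0:(n - 1L), 0:(n - 1L))

.corr_or_identity <- function(corr, a, b) {
  if (!is.null(corr)) return(corr)
  na <- n_residues(a); nb <- n_residues(b)
  if (na != nb)
    stop("structures differ in length (", na, " vs ", nb,
         "); supply an explicit correspondence")
  identity_correspondence(na)
}

# optimal proper rotation (Kabsch, base svd) mapping x onto y; both n x 3
.kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)  # maps centered x to centered y: y ~ xc %*% t(R)
  t_vec <- cy - as.numeric(R %*% cx)
  list(rotation = R, translation = t_vec)
}

#' Least-squares Ca superposition (Kabsch)
#'
#' Returns the proper rigid transform that minimizes the squared Ca
#' deviation of `mobile` onto `reference` over the corresponded residues.
#'
#' @param mobile,reference [Structure] objects.
#' @param corr A [correspondence] (mobile index, reference index); NULL for
#'   index-wise correspondence of equal-length structures.
#' @return List of class `Transform` with `rotation` (3x3, det +1) and
#'   `translation` (length-3, Angstrom); apply as `x %*% t(R) + t`.
#' @export
superpose_ca <- function(mobile, reference, corr = NULL) {
  corr <- .corr_or_identity(corr, mobile, reference)
  if (nrow(corr) < 3L) stop("need at least 3 corresponded pairs")
  xm <- ca_xyz(mobile)[corr[, 1] + 1L, , drop = FALSE]
  xr <- ca_xyz(reference)[corr[, 2] + 1L, , drop = FALSE]
  if (anyNA(xm) || anyNA(xr)) stop("missing Ca atom at a corresponded residue")
  tr <- .kabsch(xm, xr)
  class(tr) <- "Transform"
  tr
}

#' Apply a rigid transform to a Structure or coordinate matrix
#' @param x [Structure] or `n x 3` matrix.
#' @param tr Transform from [superpose_ca].
#' @return Same type as `x`.
#' @export
apply_transform <- function(x, tr) {
  f <- function(m) sweep(m %*% t(tr$rotation), 2, tr$translation, `+`)
  if (inherits(x, "Structure")) transform_coords(x, f) else f(x)
}

.deviation <- function(xm, xr, mode) {
  tr <- .kabsch(xm, xr)
  d <- sqrt(rowSums((sweep(xm %*% t(tr$rotation), 2, tr$translation, `+`) - xr)^2))
  if (mode == "mean") mean(d) else sqrt(mean(d^2))
}

#' Ca deviation after optimal superposition
#'
#' `mode = "mean"` is the mean per-residue Euclidean Ca distance (the
#' quantity reported as backbone deviation throughout this package);
#' `mode = "rms"` is the classical root-mean-square. mean <= rms always.
#'
#' @inheritParams superpose_ca
#' @param a,b [Structure] objects.
#' @param mode `"mean"` or `"rms"`.
#' @return Deviation in Angstrom.
#' @export
deviation_ca <- function(a, b, corr = NULL, mode = c("mean", "rms")) {
  mode <- match.arg(mode)
  corr <- .corr_or_identity(corr, a, b)
  if (nrow(corr) < 3L) stop("need at least 3 corresponded pairs")
  xa <- ca_xyz(a)[corr[, 1] + 1L, , drop = FALSE]
  xb <- ca_xyz(b)[corr[, 2] + 1L, , drop = FALSE]
  if (anyNA(xa) || anyNA(xb)) stop("missing Ca atom at a corresponded residue")
  .deviation(xa, xb, mode)
}

#' Full-atom deviation after optimal superposition
#'
#' Superposition is computed over all atoms shared (by atom name) between
#' corresponded residues; the deviation is reported over the same set.
#'
#' @inheritParams deviation_ca
#' @return Deviation in Angstrom.
#' @export
deviation_full_atom <- function(a, b, corr = NULL, mode = c("mean", "rms")) {
  mode <- match.arg(mode)
  corr <- .corr_or_identity(corr, a, b)
  rta <- residue_table(a); rtb <- residue_table(b)
  aa <- a$atoms; ab <- b$atoms
  keya <- paste(aa$chain, aa$resno, sep = "\r")
  keyb <- paste(ab$chain, ab$resno, sep = "\r")
  rk_a <- paste(rta$chain, rta$resno, sep = "\r")
  rk_b <- paste(rtb$chain, rtb$resno, sep = "\r")
  xa <- list(); xb <- list()
  for (k in seq_len(nrow(corr))) {
    ra <- aa[keya == rk_a[corr[k, 1] + 1L], , drop = FALSE]
    rb <- ab[keyb == rk_b[corr[k, 2] + 1L], , drop = FALSE]
    shared <- intersect(ra$elety, rb$elety)
    if (!length(shared)) next
    xa[[length(xa) + 1L]] <- as.matrix(ra[match(shared, ra$elety), c("x", "y", "z")])
    xb[[length(xb) + 1L]] <- as.matrix(rb[match(shared, rb$elety), c("x", "y", "z")])
  }
  if (!length(xa)) stop("no shared atoms over the correspondence")
  .deviation(do.call(rbind, xa), do.call(rbind, xb), mode)
}

#' TM-score normalization distance d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom.
#'
#' @param l_norm Normalization length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_norm) {
  if (l_norm <= 15) return(0.5)  # cube root undefined below 15; floor applies
  max(0.5, 1.24 * (l_norm - 15)^(1 / 3) - 1.8)
}

#' TM-score over a fixed residue correspondence
#'
#' Computes `TM = (1/L_norm) * sum 1/(1 + (d_i/d0)^2)`, maximized over
#' superpositions by iterative distance-cutoff refinement from several seed
#' fragments (no sequence-independent alignment search: the correspondence is
#' an input; the pipeline compares equal-length design and target index-wise).
#'
#' @inheritParams deviation_ca
#' @param norm_length Normalization length L_norm (default: reference residue
#'   count). Must be >= 16 unless `d0_floor_override` is TRUE.
#' @param superpose If FALSE, score the structures in their current frames
#'   without searching for a superposition.
#' @param d0_floor_override Allow `norm_length < 16` (d0 then floors at 0.5).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(a, b, corr = NULL, norm_length = NULL, superpose = TRUE,
                     d0_floor_override = FALSE) {
  corr <- .corr_or_identity(corr, a, b)
  if (nrow(corr) < 3L) stop("need at least 3 corresponded pairs")
  if (is.null(norm_length)) norm_length <- n_residues(b)
  if (norm_length < 16 && !d0_floor_override)
    stop("norm_length < 16; set d0_floor_override = TRUE to force the 0.5 floor")
  d0 <- tm_d0(norm_length)
  xa <- ca_xyz(a)[corr[, 1] + 1L, , drop = FALSE]
  xb <- ca_xyz(b)[corr[, 2] + 1L, , drop = FALSE]
  if (anyNA(xa) || anyNA(xb)) stop("missing Ca atom at a corresponded residue")
  n <- nrow(xa)
  score_from <- function(xa_t) {
    d2 <- rowSums((xa_t - xb)^2)
    min(1, sum(1 / (1 + d2 / d0^2)) / norm_length)  # capped: score in (0, 1]
  }
  if (!superpose) return(score_from(xa))
  refine <- function(sel) {
    best <- -Inf
    for (iter in 1:20) {
      if (sum(sel) < 3L) break
      tr <- .kabsch(xa[sel, , drop = FALSE], xb[sel, , drop = FALSE])
      xa_t <- sweep(xa %*% t(tr$rotation), 2, tr$translation, `+`)
      sc <- score_from(xa_t)
      if (sc > best) best <- sc else break
      d <- sqrt(rowSums((xa_t - xb)^2))
      cut <- max(d0, 4.5)
      new_sel <- d < cut
      if (sum(new_sel) < 3L) new_sel <- rank(d, ties.method = "first") <= 3L
      if (identical(new_sel, sel)) break
      sel <- new_sel
    }
    best
  }
  seeds <- list(rep(TRUE, n))
  lf <- max(5L, n %/% 4L)
  for (st in unique(pmax(1L, round(seq(1L, n - lf + 1L, length.out = 4L))))) {
    sel <- rep(FALSE, n); sel[st:(st + lf - 1L)] <- TRUE
    seeds[[length(seeds) + 1L]] <- sel
  }
  max(vapply(seeds, refine, numeric(1)))
}

# van der Waals radii (A) for SASA
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Each heavy atom is sampled with a deterministic Fibonacci point set on a
#' sphere of radius r_vdw + probe; residue SASA is the sum over its atoms.
#' Radii: C 1.70, N 1.55, O 1.52, S 1.80 Angstrom.
#'
#' @param s A [Structure].
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom.
#' @param default_radius Radius for elements outside the table (default:
#'   error on unknown element).
#' @return Numeric vector of per-residue SASA (Angstrom^2), one per residue
#'   in global residue order, with the residue table as attribute "residues".
#' @export
sasa_per_residue <- function(s, probe_radius = 1.4, n_points = 960L,
                             default_radius = NULL) {
  a <- s$atoms
  r <- .vdw_radii[a$element]
  if (anyNA(r)) {
    if (is.null(default_radius))
      stop("unknown element '", a$element[which(is.na(r))[1]],
           "' (supply default_radius)")
    r[is.na(r)] <- default_radius
  }
  areas <- cpp_sasa(as.matrix(a[, c("x", "y", "z")]), as.numeric(r),
                    probe_radius, as.integer(n_points))
  rt <- residue_table(s)
  key_atom <- match(paste(a$chain, a$resno, sep = "\r"),
                    paste(rt$chain, rt$resno, sep = "\r"))
  out <- as.numeric(tapply(areas, factor(key_atom, levels = seq_len(nrow(rt))), sum))
  out[is.na(out)] <- 0
  attr(out, "residues") <- rt
  out
}

# ---- DSSP-style secondary structure ----------------------------------------

# backbone H-bond energy (kcal/mol): E = 0.084 * (1/dON + 1/dCH - 1/dOH - 1/dCN) * 332
# H position inferred from the previous residue's carbonyl: H = N + unit(C_prev - O_prev)
.hbond_energy_matrix <- function(N, CA, C, O) {
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    v <- C[i - 1, ] - O[i - 1, ]
    nv <- sqrt(sum(v^2))
    H[i, ] <- if (nv > 1e-6) N[i, ] + v / nv else N[i, ]
  }
  E <- matrix(Inf, n, n)  # E[i, j]: donor NH of i, acceptor C=O of j
  for (i in 2:n) {
    dON <- sqrt(colSums((t(O) - N[i, ])^2))
    dCN <- sqrt(colSums((t(C) - N[i, ])^2))
    dOH <- sqrt(colSums((t(O) - H[i, ])^2))
    dCH <- sqrt(colSums((t(C) - H[i, ])^2))
    e <- 0.084 * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN) * 332
    e[abs(seq_len(n) - i) < 2] <- Inf  # no bonds to self or sequence neighbors
    e[!is.finite(e)] <- Inf            # degenerate geometry never bonds
    E[i, ] <- e
  }
  E
}

#' Secondary-structure assignment (DSSP-style, 3-state)
#'
#' Kabsch-Sander backbone hydrogen-bond energies define n-turns and bridges;
#' helices (3-, 4-, 5-turn runs) collapse to H, bridges/ladders to E,
#' everything else to L.
#'
#' @param s A [Structure] with backbone N, CA, C, O atoms.
#' @param strict Error on residues missing backbone atoms (default: label L).
#' @param energy_cutoff H-bond energy threshold (kcal/mol).
#' @return Character scalar over {H, E, L}, one letter per residue.
#' @export
assign_secondary_structure <- function(s, strict = FALSE, energy_cutoff = -0.5) {
  N <- atom_xyz(s, "N"); CA <- atom_xyz(s, "CA")
  C <- atom_xyz(s, "C"); O <- atom_xyz(s, "O")
  n <- nrow(CA)
  incomplete <- apply(is.na(N) | is.na(CA) | is.na(C) | is.na(O), 1, any)
  if (any(incomplete)) {
    if (strict) stop("missing backbone atom at residue index ",
                     which(incomplete)[1] - 1L)
    warning(sum(incomplete), " residue(s) missing backbone atoms; labeled L")
  }
  if (n < 5L) return(paste(rep("L", n), collapse = ""))
  # park incomplete residues far away and apart so they never bond
  N2 <- N; CA2 <- CA; C2 <- C; O2 <- O
  for (i in which(incomplete)) {
    far <- c(1e5 + 1e3 * i, 0, 0)
    N2[i, ] <- far; CA2[i, ] <- far + c(1, 0, 0)
    C2[i, ] <- far + c(0, 1, 0); O2[i, ] <- far + c(0, 0, 1)
  }
  E <- .hbond_energy_matrix(N2, CA2, C2, O2)
  hb <- E < energy_cutoff  # hb[i, j]: NH(i) -> CO(j)
  lab <- rep("L", n)
  # n-turns: CO(i) accepts from NH(i+k), k = 3,4,5
  for (k in c(4L, 3L, 5L)) {
    turn <- rep(FALSE, n)
    idx <- seq_len(n - k)
    turn[idx] <- hb[cbind(idx + k, idx)]
    # two consecutive k-turns at i-1 and i start a helix covering i..i+k-1
    for (i in 2:(n - k)) {
      if (turn[i - 1] && turn[i]) lab[i:(i + k - 1L)] <- "H"
    }
  }
  # bridges
  strand <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3L) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[j, i] && hb[i, j]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) { strand[i] <- TRUE; strand[j] <- TRUE }
    }
  }
  lab[strand & lab != "H"] <- "E"
  lab[incomplete] <- "L"
  paste(lab, collapse = "")
}

#' Split a secondary-structure string into element segments
#'
#' @param ss String over {H,E,L}.
#' @return Integer vector of segment ids (consecutive equal labels share id).
#' @export
ss_segments <- function(ss) {
  lab <- strsplit(ss, "")[[1]]
  cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
}
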