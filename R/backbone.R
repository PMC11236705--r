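# Ideal-geometry backbone construction (NeRF chain extension).
#
# One builder serves both the fixture generator and the toy structure
# predictor, so that a design whose per-position class weights match the
# target's secondary structure reproduces the target coordinates exactly.

# ideal bond lengths (A) and angles (deg)
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.522,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  a_n_ca_cb = 110.4, t_omega = 180, t_cb = -122.6
)

# ideal torsions per secondary-structure class
.TORSION_H <- c(phi = -57, psi = -47)
.TORSION_E <- c(phi = -139, psi = 135)
# loop torsion pattern, indexed by absolute residue position (1-based) mod 4;
# chosen once so that helix-loop-helix segments fold back into packed bundles
.LOOP_PHI <- c(-90, -70, -90, -60)
.LOOP_PSI <- c(120, -20, 120, -30)

loop_torsions <- function(pos) {
  k <- ((pos - 1L) %% length(.LOOP_PHI)) + 1L
  cbind(phi = .LOOP_PHI[k], psi = .LOOP_PSI[k])
}

#' Per-position class torsion tables
#'
#' For a chain of length `n`, returns the ideal (phi, psi) each of the three
#' secondary-structure classes (H, E, L) would impose at every position. The
#' loop class uses a fixed position-indexed turn pattern.
#'
#' @param n Chain length.
#' @return List with `phi` and `psi`, each an `n x 3` matrix (columns H, E, L).
#' @export
class_torsion_tables <- function(n) {
  lt <- loop_torsions(seq_len(n))
  list(
    phi = cbind(H = rep(.TORSION_H["phi"], n), E = rep(.TORSION_E["phi"], n),
                L = lt[, "phi"]),
    psi = cbind(H = rep(.TORSION_H["psi"], n), E = rep(.TORSION_E["psi"], n),
                L = lt[, "psi"])
  )
}

#' Torsions from secondary-structure class weights
#'
#' Blends the ideal class torsions with the given per-position weights.
#' One-hot weights reproduce the ideal geometry of the labeled class.
#'
#' @param w `n x 3` weight matrix (columns H, E, L).
#' @return List with numeric vectors `phi` and `psi` (degrees).
#' @export
torsions_from_weights <- function(w) {
  n <- nrow(w)
  tab <- class_torsion_tables(n)
  list(phi = rowSums(w * tab$phi), psi = rowSums(w * tab$psi))
}

ss_to_weights <- function(ss) {
  lab <- strsplit(ss, "")[[1]]
  if (any(!lab %in% c("H", "E", "L")))
    stop("secondary-structure string must be over {H,E,L}")
  w <- matrix(0, length(lab), 3, dimnames = list(NULL, c("H", "E", "L")))
  w[cbind(seq_along(lab), match(lab, c("H", "E", "L")))] <- 1
  w
}

.deg <- pi / 180

# signed dihedral angle (degrees) for rows of four coordinate matrices
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2) / b2n
  atan2(y, x) / .deg
}

#' Backbone phi/psi torsions of a Structure
#'
#' @param s A [Structure] with backbone N, CA, C atoms.
#' @return List of numeric vectors `phi`, `psi` (degrees; NA at chain ends).
#' @export
backbone_torsions <- function(s) {
  N <- atom_xyz(s, "N"); CA <- atom_xyz(s, "CA"); C <- atom_xyz(s, "C")
  n <- nrow(CA)
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2L) {
    phi[2:n] <- .dihedral(C[1:(n - 1), , drop = FALSE], N[2:n, , drop = FALSE],
                          CA[2:n, , drop = FALSE], C[2:n, , drop = FALSE])
    psi[1:(n - 1)] <- .dihedral(N[1:(n - 1), , drop = FALSE],
                                CA[1:(n - 1), , drop = FALSE],
                                C[1:(n - 1), , drop = FALSE],
                                N[2:n, , drop = FALSE])
  }
  list(phi = phi, psi = psi)
}

#' Classify residues by nearest ideal torsion class
#'
#' Assigns each residue the secondary-structure class (H, E or L) whose
#' ideal torsions are angularly closest to the measured backbone phi/psi —
#' a purely local, conformation-based classification, unlike the
#' hydrogen-bond-based [assign_secondary_structure].
#'
#' @param s A [Structure].
#' @return Character vector over {H, E, L}, one per residue.
#' @export
torsion_class <- function(s) {
  tor <- backbone_torsions(s)
  n <- length(tor$phi)
  tab <- class_torsion_tables(n)
  angdist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  cls <- vapply(seq_len(n), function(i) {
    d <- vapply(1:3, function(c3) {
      dp <- if (is.na(tor$phi[i])) 0 else angdist(tor$phi[i], tab$phi[i, c3])
      ds <- if (is.na(tor$psi[i])) 0 else angdist(tor$psi[i], tab$psi[i, c3])
      dp + ds
    }, numeric(1))
    c("H", "E", "L")[which.min(d)]
  }, character(1))
  cls
}

# place atom D given A, B, C, bond |CD|, angle B-C-D, dihedral A-B-C-D (deg,
# standard IUPAC sign convention)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * .deg; chi <- torsion * .deg
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), -sin(th) * sin(chi))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  c + bond * 0 + cbind(bc, m2, n) %*% d2
}

#' Build an ideal backbone from torsions
#'
#' Sequentially places N, CA, C, O for each residue with ideal bond lengths
#' and angles, omega fixed at 180 degrees.
#'
#' @param phi,psi Numeric vectors of torsions (degrees), length n. `phi[1]`
#'   and the carbonyl torsion of the last residue use the given values with
#'   the standard NeRF bootstrap for the first residue.
#' @return List of `n x 3` matrices `n`, `ca`, `c`, `o`.
#' @export
build_backbone <- function(phi, psi) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 1L)
  N <- CA <- C <- O <- matrix(0, n_res, 3)
  # bootstrap first residue in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$b_n_ca, 0, 0)
  th <- .BB$a_n_ca_c * .deg
  C[1, ] <- CA[1, ] + .BB$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           .BB$b_c_n, .BB$a_ca_c_n, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            .BB$b_n_ca, .BB$a_c_n_ca, .BB$t_omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           .BB$b_ca_c, .BB$a_n_ca_c, phi[i])
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         .BB$b_c_o, .BB$a_ca_c_o, psi[i] + 180)
  }
  list(n = N, ca = CA, c = C, o = O)
}

# pseudo side-chain extension (A) beyond CA along the CA->CB direction,
# coarse size classes; G has no side-chain atoms, A stops at CB
.sc_extent <- c(
  A = 0, C = 2.3, D = 2.9, E = 3.4, F = 3.4, G = 0, H = 3.2, I = 2.9,
  K = 3.9, L = 3.0, M = 3.4, N = 2.9, P = 2.3, Q = 3.4, R = 4.3, S = 2.3,
  T = 2.3, V = 2.3, W = 3.7, Y = 3.8
)

place_cb <- function(N, CA, C) {
  t(vapply(seq_len(nrow(CA)), function(i) {
    as.numeric(nerf_place(C[i, ], N[i, ], CA[i, ],
                          .BB$b_ca_cb, .BB$a_n_ca_cb, .BB$t_cb))
  }, numeric(3)))
}

#' Assemble a Structure from backbone coordinate matrices
#'
#' Adds CB and a single pseudo side-chain centroid atom (SC, carbon radius)
#' per residue according to the sequence; glycine gets neither, alanine only
#' CB. This coarse side-chain representation is what the package's SASA and
#' layer metrics see for generated structures.
#'
#' @param N,CA,C,O `n x 3` backbone coordinate matrices (`O` may be NULL).
#' @param seq One-letter sequence of length n.
#' @param chain Chain id.
#' @param resno_start First author residue number.
#' @return A [Structure].
#' @export
build_structure_from_backbone <- function(N, CA, C, O = NULL, seq,
                                          chain = "A", resno_start = 1L) {
  seq <- validate_sequence(seq)
  n_res <- nrow(CA)
  stopifnot(nchar(seq) == n_res)
  letters1 <- strsplit(seq, "")[[1]]
  CB <- place_cb(N, CA, C)
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    let <- letters1[i]
    elety <- c("N", "CA", "C")
    elem <- c("N", "C", "C")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ])
    if (!is.null(O)) {
      elety <- c(elety, "O"); elem <- c(elem, "O"); xyz <- rbind(xyz, O[i, ])
    }
    if (let != "G") {
      elety <- c(elety, "CB"); elem <- c(elem, "C"); xyz <- rbind(xyz, CB[i, ])
      ext <- .sc_extent[[let]]
      if (ext > 0) {
        dir <- CB[i, ] - CA[i, ]
        dir <- dir / sqrt(sum(dir^2))
        elety <- c(elety, "SC"); elem <- c(elem, "C")
        xyz <- rbind(xyz, CA[i, ] + (sqrt(sum((CB[i, ] - CA[i, ])^2)) + ext) * dir)
      }
    }
    rows[[i]] <- data.frame(
      chain = chain, resno = resno_start + i - 1L, resname = .aa123[[let]],
      elety = elety, element = elem,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  }
  Structure(do.call(rbind, rows))
}

#' Build an ideal-geometry structure from a secondary-structure string
#'
#' @param ss String over {H,E,L}.
#' @param seq Optional sequence (defaults to the class-ideal A/V/G encoding).
#' @param chain Chain id.
#' @return A [Structure].
#' @export
build_structure_from_ss <- function(ss, seq = NULL, chain = "A") {
  w <- ss_to_weights(ss)
  if (is.null(seq)) seq <- init_sequence_from_ss(ss)
  tor <- torsions_from_weights(w)
  bb <- build_backbone(tor$phi, tor$psi)
  build_structure_from_backbone(bb$n, bb$ca, bb$c, bb$o, seq, chain = chain)
}
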