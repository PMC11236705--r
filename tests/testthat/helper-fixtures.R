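# shared fixtures, built once per test run

bundle40 <- generate_fixture(fixture_spec("helix_bundle", 40))
membrane60 <- generate_fixture(fixture_spec("membrane_like_bundle", 60))
helix20 <- generate_fixture(fixture_spec("helix", 20))

# minimal hand-written PDB: one alanine, five heavy atoms
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.697   7.135  -4.892  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.407   7.575  -5.797  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      12.226   4.666  -4.898  1.00  0.00           C",
    "TER       6      ALA A   1",
    "END"), path)
  path
}

# two altlocs for one CA atom: A at occupancy 0.6, B at 0.4
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       2.458   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.932   2.861   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.450   2.852   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.079   1.797   0.000  1.00  0.00           O",
    "ATOM     10  N   VAL A   3       6.050   4.040   0.000  1.00  0.00           N",
    "ATOM     11  CA  VAL A   3       7.500   4.180   0.000  1.00  0.00           C",
    "ATOM     12  C   VAL A   3       8.100   5.580   0.000  1.00  0.00           C",
    "ATOM     13  O   VAL A   3       7.400   6.590   0.000  1.00  0.00           O",
    "TER      14      VAL A   3",
    "END"), path)
  path
}

rigid_copy <- function(s, angle_deg = 30, axis = c(0, 0, 1), shift = c(5, -3, 2)) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  solufold:::transform_coords(s, function(xyz) sweep(xyz %*% t(R), 2, shift, `+`))
}
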