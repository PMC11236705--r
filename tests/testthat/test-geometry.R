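test_that("superposition recovers constructed rigid transforms", {
  s <- bundle40$structure
  # pure translation
  moved <- solufold:::transform_coords(s, function(x) sweep(x, 2, c(5, 0, 0), `+`))
  tr <- superpose_ca(moved, s)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(-5, 0, 0), tolerance = 1e-9)
  # identity
  tr0 <- superpose_ca(s, s)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(deviation_ca(s, s), 0, tolerance = 1e-12)
  # constructed 90-degree rotation about z on an asymmetric 4-point toy
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 5, 1), c(1, 2, 7))
  mk <- function(m) {
    Structure(data.frame(chain = "A", resno = seq_len(nrow(m)), resname = "ALA",
                         elety = "CA", element = "C",
                         x = m[, 1], y = m[, 2], z = m[, 3]))
  }
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rotated <- mk(xyz %*% t(Rz))
  rec <- superpose_ca(rotated, mk(xyz))
  expect_equal(rec$rotation %*% Rz, diag(3), tolerance = 1e-9)
  expect_equal(det(rec$rotation), 1, tolerance = 1e-12)
})

test_that("superposition residual matches a brute-force rotation grid on a small toy", {
  set.seed(42)
  xyz <- matrix(rnorm(18, sd = 3), 6, 3)
  mk <- function(m) Structure(data.frame(chain = "A", resno = seq_len(nrow(m)),
                                         resname = "GLY", elety = "CA",
                                         element = "C", x = m[, 1], y = m[, 2],
                                         z = m[, 3]))
  target <- xyz + matrix(rnorm(18, sd = 0.4), 6, 3)
  opt <- deviation_ca(mk(xyz), mk(target), mode = "rms")
  # brute force: coarse 3-angle grid then local refinement (5 -> 0.2 deg)
  rotm <- function(a, b, g) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  xc <- sweep(xyz, 2, colMeans(xyz)); yc <- sweep(target, 2, colMeans(target))
  rms_at <- function(a, b, g) sqrt(mean(rowSums((xc %*% t(rotm(a, b, g)) - yc)^2)))
  best <- c(0, 0, 0); step <- 20 * pi / 180; bv <- rms_at(0, 0, 0)
  for (rep in 1:8) {
    grid <- expand.grid(a = best[1] + step * (-3:3), b = best[2] + step * (-3:3),
                        g = best[3] + step * (-3:3))
    vals <- mapply(rms_at, grid$a, grid$b, grid$g)
    k <- which.min(vals)
    best <- as.numeric(grid[k, ]); bv <- vals[k]
    step <- step / 2.5
  }
  expect_equal(opt, bv, tolerance = 1e-3)
  expect_lte(opt, bv + 1e-9)  # Kabsch is the true minimum
})

test_that("deviation metrics: hand-computed values, symmetry, mean <= rms", {
  # post-superposition distances {0, 0, 2}: mean 2/3, rms sqrt(4/3)
  d <- c(0, 0, 2)
  expect_equal(mean(d), 0.6667, tolerance = 1e-4)
  expect_equal(sqrt(mean(d^2)), 1.1547, tolerance = 1e-4)
  s <- bundle40$structure
  for (k in 1:5) {
    pert <- add_backbone_noise(s, 0.8, rng_seed = k)
    m1 <- deviation_ca(s, pert); m2 <- deviation_ca(pert, s)
    expect_equal(m1, m2, tolerance = 1e-9)
    expect_lte(deviation_ca(s, pert, mode = "mean"),
               deviation_ca(s, pert, mode = "rms") + 1e-12)
    # rigid pre-transform invariance
    expect_equal(deviation_ca(rigid_copy(pert, 70, c(1, 2, 0), c(-4, 2, 9)), s),
                 m1, tolerance = 1e-9)
  }
})

test_that("full-atom deviation reduces to Ca deviation on Ca-only structures and matches brute force", {
  s <- bundle40$structure
  ca_only <- Structure(s$atoms[s$atoms$elety == "CA", ])
  pert <- add_backbone_noise(ca_only, 1, rng_seed = 3)
  expect_equal(deviation_full_atom(ca_only, pert),
               deviation_ca(ca_only, pert), tolerance = 1e-12)
  expect_equal(deviation_full_atom(s, s), 0, tolerance = 1e-12)
  # brute-force oracle: displace one residue's side chain, enumerate shared atoms
  s2 <- s
  sel <- s2$atoms$resno == 5L & s2$atoms$elety %in% c("CB", "SC")
  s2$atoms$x[sel] <- s2$atoms$x[sel] + 1
  xa <- as.matrix(s$atoms[, c("x", "y", "z")])
  xb <- as.matrix(s2$atoms[, c("x", "y", "z")])  # same atom names/order
  tr <- solufold:::.kabsch(xb, xa)
  dd <- sqrt(rowSums((sweep(xb %*% t(tr$rotation), 2, tr$translation, `+`) - xa)^2))
  expect_equal(deviation_full_atom(s2, s), mean(dd), tolerance = 1e-9)
})

test_that("TM-score: self-comparison 1, d0 formula and floor, displaced = 0.5 unsuperposed", {
  s <- generate_fixture(fixture_spec("helix_bundle", 50))$structure
  expect_equal(tm_score(s, s), 1.0, tolerance = 1e-9)
  expect_equal(tm_d0(21), 0.5)  # 1.24*(21-15)^(1/3)-1.8 = 0.4532 floored
  expect_equal(1.24 * (21 - 15)^(1/3) - 1.8, 0.4532, tolerance = 1e-3)
  expect_equal(tm_d0(50), 1.24 * 35^(1/3) - 1.8, tolerance = 1e-12)
  d0 <- tm_d0(50)
  shifted <- solufold:::transform_coords(s, function(x) sweep(x, 2, c(d0, 0, 0), `+`))
  expect_equal(tm_score(shifted, s, superpose = FALSE), 0.5, tolerance = 1e-12)
  expect_error(tm_score(s, s, norm_length = 12), "norm_length")
  expect_equal(tm_score(s, s, norm_length = 12, d0_floor_override = TRUE), 1,
               tolerance = 1e-9)
})

test_that("TM-score is rigid-invariant and decreases with growing noise", {
  s <- bundle40$structure
  expect_equal(tm_score(rigid_copy(s), s), 1.0, tolerance = 1e-6)
  for (seed in 1:3) {
    tms <- vapply(c(0, 0.5, 1, 2), function(sig) {
      if (sig == 0) return(tm_score(s, s))
      tm_score(add_backbone_noise(s, sig, rng_seed = seed), s)
    }, numeric(1))
    expect_true(all(diff(tms) <= 1e-9))
  }
})

test_that("SASA: isolated sphere is analytic, enclosure gives 0, tangent spheres stay full", {
  mk <- function(xyz, elem = "C") {
    Structure(data.frame(chain = "A", resno = seq_len(nrow(xyz)),
                         resname = "GLY", elety = "X", element = elem,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  }
  # single carbon: 4*pi*(1.7+1.4)^2
  a <- sasa_per_residue(mk(matrix(0, 1, 3)))
  expect_equal(as.numeric(a), 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  # two atoms at exactly 2*(r+probe): tangent, both spheres fully exposed
  b <- sasa_per_residue(mk(rbind(c(0, 0, 0), c(2 * 3.1, 0, 0))))
  expect_equal(as.numeric(b), rep(4 * pi * 3.1^2, 2), tolerance = 1)
  # atom enclosed by a tight shell of neighbors
  sph <- solufold:::cpp_sasa
  pts <- matrix(0, 27, 3); k <- 1
  for (x in -1:1) for (y in -1:1) for (z in -1:1) {
    pts[k, ] <- 2.2 * c(x, y, z); k <- k + 1
  }
  areas <- sph(pts, rep(1.7, 27), 1.4, 960L)
  expect_equal(areas[14], 0)  # the central atom
  expect_error(sasa_per_residue(mk(matrix(0, 1, 3), elem = "ZZ")), "unknown element")
  expect_silent(sasa_per_residue(mk(matrix(0, 1, 3), elem = "ZZ"),
                                 default_radius = 1.8))
})

test_that("SASA totals do not increase when atoms are added; per-residue values non-negative", {
  s <- membrane60$structure
  sasa_full <- sasa_per_residue(s)
  expect_true(all(sasa_full >= 0))
  sub <- Structure(s$atoms[s$atoms$resno <= 30L, ])
  sasa_sub <- sasa_per_residue(sub)
  expect_gte(sum(sasa_sub), sum(sasa_full[1:30]) - 1e-9)
})

test_that("secondary structure: ideal helix is H inside, lone extended chain is L", {
  hel <- generate_fixture(fixture_spec("helix", 20))
  lab <- strsplit(assign_secondary_structure(hel$structure), "")[[1]]
  expect_true(all(lab[3:18] == "H"))
  ext <- generate_fixture(fixture_spec("strand", 12))
  expect_equal(assign_secondary_structure(ext$structure), strrep("L", 12))
})

test_that("antiparallel hairpin strands carry H-bonds below the energy cutoff and label E", {
  fx <- generate_fixture(fixture_spec("beta_hairpin", 20))
  s <- fx$structure
  N <- solufold:::atom_xyz(s, "N"); CA <- ca_xyz(s)
  C <- solufold:::atom_xyz(s, "C"); O <- solufold:::atom_xyz(s, "O")
  E <- solufold:::.hbond_energy_matrix(N, CA, C, O)
  strand1 <- 1:8; strand2 <- 13:20
  cross <- E[strand1, strand2]
  expect_gte(sum(cross < -0.5), 3)  # direct evaluation of the energy formula
  lab <- strsplit(assign_secondary_structure(s), "")[[1]]
  expect_gte(mean(lab[c(3:7, 14:18)] == "E"), 0.8)
})

test_that("missing backbone atoms give L with a warning, or error in strict mode", {
  s <- helix20$structure
  s <- Structure(s$atoms[!(s$atoms$resno == 10L & s$atoms$elety == "O"), ])
  expect_warning(lab <- assign_secondary_structure(s), "missing backbone")
  expect_equal(substr(lab, 10, 10), "L")
  expect_error(assign_secondary_structure(s, strict = TRUE), "missing backbone")
})
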