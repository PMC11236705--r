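make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[[1]], sequence = "AAAA", tm_to_target = r[[2]],
               mean_plddt = r[[3]], best_evalue = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("filters enforce strict inequalities at the standard and rhomboid gates", {
  recs <- make_records(
    list("keep", 0.85, 0.82, 0.2),
    list("tm_at_gate", 0.80, 0.82, 0.2),     # rejected: strict >
    list("plddt_at_gate", 0.85, 0.80, 0.2),  # rejected
    list("evalue_low", 0.85, 0.82, 0.1),     # rejected
    list("rhomboid_zone", 0.76, 0.76, 0.2))  # rejected at 0.80, kept at 0.75
  std <- apply_filters(recs, filter_criteria())
  expect_equal(std$id, "keep")
  rho <- apply_filters(recs, filter_criteria(tm_min = 0.75, plddt_min = 0.75))
  expect_setequal(rho$id, c("keep", "tm_at_gate", "plddt_at_gate", "rhomboid_zone"))
  # missing e-value passes by default, rejected under strict_evalue
  na_rec <- make_records(list("novel", 0.9, 0.9, NA_real_))
  expect_equal(nrow(apply_filters(na_rec, filter_criteria())), 1L)
  expect_equal(nrow(apply_filters(na_rec, filter_criteria(), strict_evalue = TRUE)), 0L)
})

test_that("apply_filters output is a subset, order-preserving, and idempotent", {
  set.seed(3)
  recs <- do.call(rbind, lapply(1:30, function(i)
    data.frame(id = paste0("d", i), sequence = "AAAA",
               tm_to_target = runif(1, 0.5, 1), mean_plddt = runif(1, 0.5, 1),
               best_evalue = runif(1, 0.01, 1), stringsAsFactors = FALSE)))
  out <- apply_filters(recs, filter_criteria())
  expect_true(all(out$id %in% recs$id))
  expect_equal(out$id, recs$id[recs$id %in% out$id])  # order preserved
  expect_identical(apply_filters(out, filter_criteria()), out)
  expect_error(filter_criteria(tm_min = 1.01), "\\(0, 1\\]")
})

test_that("sequence recovery counts matches over the right denominator", {
  expect_equal(sequence_recovery("AAAA", "AAAA"), 100)
  expect_equal(sequence_recovery("AAAA", "AAGG"), 50)
  expect_equal(sequence_recovery("AAAA", "AAGG", subset = c(0, 1)), 100)
  expect_equal(sequence_recovery("AAAA", "AAGG", subset = c(2, 3)), 0)
  expect_error(sequence_recovery("AAA", "AAAA"), "mismatch")
  expect_error(sequence_recovery("AAAA", "AAGG", subset = 7), "out of range")
})

test_that("layer classification partitions residues at the 20/40 SASA thresholds", {
  ext <- generate_fixture(fixture_spec("strand", 5))$structure
  lay <- classify_layers(ext)
  expect_equal(lay, rep("surface", 5))  # fully extended peptide is all surface
  expect_equal(classify_layers(ext, sasa = c(10, 19.9, 20, 30, 40.1)),
               c("core", "core", "boundary", "boundary", "surface"))
  full <- classify_layers(membrane60$structure)
  expect_length(full, 60L)
  expect_true(all(full %in% c("core", "boundary", "surface")))
  expect_true("core" %in% full)  # bundle interior is buried by construction
})

test_that("surface hydrophobic fraction uses the exact GPAVILMFYW set over SASA > 40", {
  ext_leu <- build_structure_from_ss(strrep("E", 8), seq = strrep("L", 8))
  expect_equal(surface_hydrophobic_fraction(ext_leu), 1)
  ext_lys <- build_structure_from_ss(strrep("E", 8), seq = strrep("K", 8))
  expect_equal(surface_hydrophobic_fraction(ext_lys), 0)
  # mixed extended fixture: count by hand
  seq <- "LKLKLKLKLK"
  ext_mix <- build_structure_from_ss(strrep("E", 10), seq = seq)
  sasa <- sasa_per_residue(ext_mix)
  expect_true(all(sasa > 40))
  expect_equal(surface_hydrophobic_fraction(ext_mix), 0.5)
})

test_that("contact order: lone helix has no qualifying contacts; hairpin matches brute force", {
  hel <- generate_fixture(fixture_spec("helix", 30))
  co <- ss_contact_order(hel$structure, ss = hel$ss)
  expect_true(co$no_contacts)
  expect_equal(co$mean_separation, 0)
  # brute-force double loop over all pairs (independent oracle)
  brute <- function(s, ss, cutoff = 8, minsep = 5) {
    ca <- ca_xyz(s); n <- nrow(ca)
    seg <- ss_segments(ss)
    seps <- c()
    for (i in 1:n) for (j in 1:n) {
      if (j <= i) next
      if (j - i < minsep) next
      if (seg[i] == seg[j]) next
      if (sqrt(sum((ca[i, ] - ca[j, ])^2)) > cutoff) next
      seps <- c(seps, j - i)
    }
    if (is.null(seps)) 0 else mean(seps)
  }
  for (fx in list(generate_fixture(fixture_spec("beta_hairpin", 20)),
                  bundle40, membrane60,
                  generate_fixture(fixture_spec("barrel_like", 85, loop_len = 3)),
                  generate_fixture(fixture_spec("tim_like", 150, loop_len = 3)))) {
    co <- ss_contact_order(fx$structure, ss = fx$ss)
    expect_equal(co$mean_separation, brute(fx$structure, fx$ss), tolerance = 1e-12)
    expect_equal(co$relative, co$mean_separation / n_residues(fx$structure),
                 tolerance = 1e-12)
  }
})

test_that("TIM-like topology has strictly greater contact order than a helix bundle", {
  tim <- generate_fixture(fixture_spec("tim_like", 150, loop_len = 3))
  co_tim <- ss_contact_order(tim$structure, ss = tim$ss)
  co_bun <- ss_contact_order(bundle40$structure, ss = bundle40$ss)
  expect_gt(co_tim$mean_separation, co_bun$mean_separation)
})

test_that("BLAST best e-value parsing: minimum per query, scientific notation, errors", {
  p <- tempfile(fileext = ".tsv")
  line <- function(q, ev) paste(q, "hit", "90.0", "100", "5", "0", "1", "100",
                                "1", "100", ev, "200", sep = "\t")
  writeLines(c(line("q1", "0.5"), line("q1", "0.003"), line("q2", "3e-12")), p)
  ev <- parse_blast_best_evalue(p)
  expect_equal(ev[["q1"]], 0.003)
  expect_equal(ev[["q2"]], 3e-12)
  writeLines(character(0), p)
  expect_length(parse_blast_best_evalue(p), 0L)
  writeLines("only\tthree\tfields", p)
  expect_error(parse_blast_best_evalue(p), "line 1")
})

test_that("reprediction scoring fills the record and is deterministic", {
  tgt <- bundle40$structure
  ideal <- init_sequence_from_ss(bundle40$ss)
  rec <- repredict_and_score(ideal, toy_predictor(), tgt, id = "ideal")
  expect_gte(rec$tm_to_target, 0.9)
  set.seed(2)
  scrambled <- paste(sample(strsplit(ideal, "")[[1]]), collapse = "")
  rec2 <- repredict_and_score(scrambled, toy_predictor(), tgt, id = "scrambled")
  expect_lt(rec2$tm_to_target, rec$tm_to_target)
  # a low-purity sequence (mixed class propensities) scores lower confidence
  mixed <- strrep("S", 40)
  rec3 <- repredict_and_score(mixed, toy_predictor(), tgt, id = "mixed")
  expect_lt(rec3$mean_plddt, rec$mean_plddt)
  expect_identical(rec, repredict_and_score(ideal, toy_predictor(), tgt, id = "ideal"))
  expect_error(repredict_and_score(strrep("A", 10), toy_predictor(), tgt), "length")
})
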