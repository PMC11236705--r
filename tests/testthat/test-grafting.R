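test_that("epitope map: identity self-map has TM 1; coverage errors; low-TM warning", {
  s <- bundle40$structure
  n <- n_residues(s)
  corr <- identity_correspondence(n)
  m <- build_epitope_map(s, s, corr, epitope = 10:16)
  expect_equal(m$superposition_tm, 1, tolerance = 1e-9)
  expect_false(m$below_threshold)
  expect_equal(m$pairs[, "donor"], 10:16, ignore_attr = TRUE)
  expect_equal(m$pairs[, "scaffold"], 10:16, ignore_attr = TRUE)
  expect_error(build_epitope_map(s, s, correspondence(0:9, 0:9), epitope = 12),
               "not covered")
  # structurally distant donor: warning flag below the 0.7 gate
  donor <- add_backbone_noise(s, 6, rng_seed = 2)
  expect_warning(m2 <- build_epitope_map(s, donor, corr, epitope = 10:16),
                 "0.7")
  expect_true(m2$below_threshold)
  expect_lte(m2$superposition_tm, 0.7)
})

test_that("sequence transplantation pastes exactly the mapped letters", {
  scaffold <- strrep("A", 100)
  donor <- paste(rep("KR", 50), collapse = "")
  s <- bundle40$structure
  # empty map: unchanged
  m0 <- list(pairs = cbind(donor = integer(0), scaffold = integer(0)))
  expect_equal(transplant_sequence(scaffold, donor, m0), scaffold)
  # full identity map: donor sequence
  mfull <- list(pairs = cbind(donor = 0:99, scaffold = 0:99))
  expect_equal(transplant_sequence(scaffold, donor, mfull), donor)
  # 7-residue epitope: Hamming distance <= 7
  m7 <- list(pairs = cbind(donor = 20:26, scaffold = 50:56))
  out <- transplant_sequence(scaffold, donor, m7)
  expect_equal(nchar(out), 100L)
  hamming <- sum(strsplit(out, "")[[1]] != strsplit(scaffold, "")[[1]])
  expect_lte(hamming, 7L)
  expect_equal(substr(out, 51, 57), substr(donor, 21, 27))
  expect_error(transplant_sequence(scaffold, donor,
                                   list(pairs = cbind(donor = 150, scaffold = 1))),
               "out of range")
})

test_that("transplant is idempotent and commutes for disjoint maps", {
  scaffold <- strrep("A", 60)
  donor <- strrep("W", 60)
  m1 <- list(pairs = cbind(donor = 0:4, scaffold = 10:14))
  m2 <- list(pairs = cbind(donor = 20:24, scaffold = 40:44))
  once <- transplant_sequence(scaffold, donor, m1)
  expect_equal(transplant_sequence(once, donor, m1), once)
  ab <- transplant_sequence(transplant_sequence(scaffold, donor, m1), donor, m2)
  ba <- transplant_sequence(transplant_sequence(scaffold, donor, m2), donor, m1)
  expect_equal(ab, ba)
})

test_that("chimera screening gates on confidence and scaffold TM without mutating input", {
  scaffold <- bundle40$structure
  native <- init_sequence_from_ss(bundle40$ss)
  # graft loop-preferring letters into a helix span: toy confidence drops there
  bad_map <- list(pairs = cbind(donor = 0:5, scaffold = 3:8))
  chimera_bad <- transplant_sequence(native, strrep("P", 40), bad_map)
  out <- screen_chimeras(c(native, chimera_bad), toy_predictor(), scaffold,
                         plddt_min = 0.90, tm_min = 0.8)
  expect_equal(out$scores$sequence, c(native, chimera_bad))
  expect_true(out$scores$pass[1])       # unmodified scaffold sequence passes
  expect_true(native %in% out$passing)
  pred_bad <- predict_structure(toy_predictor(), chimera_bad,
                                predictor_config(n_recycles = 3L,
                                                 ensemble_size = 1L))[[1]]
  pred_ok <- predict_structure(toy_predictor(), native,
                               predictor_config(n_recycles = 3L,
                                                ensemble_size = 1L))[[1]]
  expect_lt(mean(pred_bad$plddt[4:9]), mean(pred_ok$plddt[4:9]))
  empty <- screen_chimeras(character(0), toy_predictor(), scaffold)
  expect_equal(nrow(empty$scores), 0L)
  expect_length(empty$passing, 0L)
})

test_that("Foldseek hit parsing applies the TM gate and sorts best-first", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("q\tt1\t0.92", "q\tt2\t0.65", "q\tt3\t0.78"), p)
  hits <- parse_foldseek_hits(p)
  expect_equal(hits$target, c("t1", "t3"))
  expect_equal(hits$tm, c(0.92, 0.78))
  writeLines("q\tt1\tnot_a_number", p)
  expect_error(parse_foldseek_hits(p), "line 1")
})

test_that("epitope TSV round-trips into a correspondence", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("donor_index\tscaffold_index", "3\t10", "4\t11", "5\t12"), p)
  ep <- read_epitope_tsv(p)
  expect_equal(ep$epitope, 3:5)
  expect_equal(ep$corr[, 1], 3:5, ignore_attr = TRUE)
})
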