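test_that("backbone noise has the stated moments, is seeded, and sigma 0 is identity", {
  s <- membrane60$structure
  expect_identical(add_backbone_noise(s, 0, 1), s)
  expect_error(add_backbone_noise(s, -0.1, 1), ">= 0")
  a <- add_backbone_noise(s, 0.5, rng_seed = 7)
  b <- add_backbone_noise(s, 0.5, rng_seed = 7)
  expect_identical(a, b)
  # empirical per-axis sd over many atoms (law of large numbers band)
  big <- Structure(do.call(rbind, lapply(1:40, function(k) {
    at <- s$atoms; at$chain <- sprintf("%s%02d", "c", k); at
  })))
  n1 <- add_backbone_noise(big, 0.1, rng_seed = 3)
  d <- as.matrix(n1$atoms[, c("x", "y", "z")]) - as.matrix(big$atoms[, c("x", "y", "z")])
  expect_gt(nrow(d), 10000)
  expect_true(all(apply(d, 2, stats::sd) > 0.095 & apply(d, 2, stats::sd) < 0.105))
})

test_that("sampling bias: +bonus on the 10 polar residues, -penalty on alanine", {
  b <- build_sampling_bias(1, 1)
  expect_equal(sum(b == 1), 10L)
  expect_equal(unname(b["A"]), -1)
  expect_equal(sum(b == 0), 9L)
  expect_setequal(names(b)[b == 1], c("D","E","H","K","N","Q","R","S","T","Y"))
  expect_equal(build_sampling_bias(0, 0), setNames(numeric(20), aa_alphabet()))
})

test_that("polar fraction rises monotonically with the polar bonus", {
  s <- membrane60$structure
  polar_frac <- function(bonus) {
    seqs <- sample_sequences(s, mock_uniform_sampler(),
                             sampler_options(n_sequences = 30,
                                             bias = build_sampling_bias(bonus, 0),
                                             rng_seed = 11))
    chars <- unlist(strsplit(seqs, ""))
    mean(chars %in% aa_polar())
  }
  fr <- vapply(c(0, 1, 2), polar_frac, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("sample_sequences enforces count, fixed positions, cys mask, determinism", {
  s <- bundle40$structure
  opts <- sampler_options(n_sequences = 2L, fixed_positions = c("0" = "M"),
                          rng_seed = 3)
  seqs <- sample_sequences(s, mock_uniform_sampler(), opts)
  expect_length(seqs, 2L)
  expect_true(all(substr(seqs, 1, 1) == "M"))
  expect_identical(seqs, sample_sequences(s, mock_uniform_sampler(), opts))
  # fixed positions survive bias and noise together
  opts2 <- sampler_options(n_sequences = 4L,
                           fixed_positions = c("0" = "M", "10" = "W"),
                           bias = build_sampling_bias(2, 1),
                           backbone_noise_sigma = 0.3, rng_seed = 9)
  seqs2 <- sample_sequences(s, mock_burial_sampler(), opts2)
  expect_true(all(substr(seqs2, 1, 1) == "M" & substr(seqs2, 11, 11) == "W"))
  expect_error(sample_sequences(s, mock_uniform_sampler(),
                                sampler_options(fixed_positions = c("400" = "M"))),
               "out of range")
})

test_that("no cysteine is ever sampled with the mask on", {
  s <- helix20$structure
  seqs <- sample_sequences(s, mock_uniform_sampler(),
                           sampler_options(n_sequences = 500L, rng_seed = 1))
  expect_false(any(grepl("C", seqs)))
})

test_that("uniform mock sampler letter frequencies are uniform within multinomial bounds", {
  s <- helix20$structure
  seqs <- sample_sequences(s, mock_uniform_sampler(),
                           sampler_options(n_sequences = 500L, mask_cys = TRUE,
                                           rng_seed = 2))
  chars <- unlist(strsplit(seqs, ""))
  n <- length(chars)  # 10,000 draws
  p <- 1 / 19
  counts <- table(factor(chars, levels = setdiff(aa_alphabet(), "C")))
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < 3.5 * sigma))
  expect_equal(sum(counts), n)
})

test_that("fixed-position files round-trip into sampler options", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tindex\tletter", "A\t0\tM", "A\t5\tW", "B\t2\tK"), p)
  fp <- read_fixed_positions(p, chain = "A")
  expect_equal(fp, c("0" = "M", "5" = "W"))
  expect_length(read_fixed_positions(p), 3L)
})

test_that("functionalization presets fix the complementary position sets", {
  fx <- membrane60
  tm_mask <- strsplit(fx$ss, "")[[1]] == "H"
  all_fixed <- fixed_positions_preset(fx$structure, tm_mask, "transmembrane-all")
  surf_fixed <- fixed_positions_preset(fx$structure, tm_mask, "transmembrane-surface")
  n <- n_residues(fx$structure)
  # every loop position is fixed under both presets
  loops <- which(!tm_mask) - 1L
  expect_true(all(as.character(loops) %in% names(all_fixed)))
  expect_true(all(as.character(loops) %in% names(surf_fixed)))
  # the surface-only preset fixes more (designs fewer) positions
  expect_gte(length(surf_fixed), length(all_fixed))
  expect_lt(length(all_fixed), n)
  # fixed letters equal the native sequence at those positions
  seqc <- strsplit(extract_sequence(fx$structure), "")[[1]]
  idx <- as.integer(names(all_fixed))
  expect_equal(unname(all_fixed), seqc[idx + 1L])
})
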