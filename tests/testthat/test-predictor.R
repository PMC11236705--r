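test_that("PSSM decoding: softmax + argmax, C masked, ties break low", {
  p <- pssm(matrix(0, 12, 20))
  dec <- pssm_decode(p)
  expect_equal(dec$sequence, strrep("A", 12))  # tie-break to lowest index
  expect_equal(rowSums(dec$probabilities), rep(1, 12), tolerance = 1e-12)
  expect_equal(unname(dec$probabilities[1, "C"]), 0, tolerance = 1e-12)
  expect_equal(unname(dec$probabilities[1, "A"]), 1 / 19, tolerance = 1e-12)
  m <- matrix(0, 12, 20); m[1, 19] <- 10  # W at position 1
  dec2 <- pssm_decode(pssm(m))
  expect_equal(substr(dec2$sequence, 1, 1), "W")
  expect_gt(dec2$probabilities[1, "W"], 0.99)
})

test_that("decoded sequences never contain cysteine", {
  set.seed(99)
  for (k in 1:50) {
    m <- matrix(rnorm(15 * 20, sd = 5), 15, 20)
    expect_false(grepl("C", pssm_decode(pssm(m))$sequence))
  }
})

test_that("toy propensity table: rows normalized, stated maxima, fixed member perturbations", {
  P <- toy_propensity_table(1)
  expect_equal(rowSums(P), rep(1, 20), ignore_attr = TRUE)
  expect_equal(names(which.max(P["A", ])), "H")
  expect_equal(names(which.max(P["V", ])), "E")
  expect_equal(names(which.max(P["G", ])), "L")
  for (m in 2:5) {
    expect_false(identical(toy_propensity_table(m), P))
    expect_equal(toy_propensity_table(m), toy_propensity_table(m),
                 tolerance = 0)  # fixed constants, not random
  }
})

test_that("toy predictor: all-A gives a confident helix, uniform PSSM is low confidence", {
  pred <- predict_structure(toy_predictor(), strrep("A", 20),
                            predictor_config(ensemble_size = 1L))[[1]]
  expect_equal(pred$labels, strrep("H", 20))
  expect_true(all(pred$plddt > 0.9))
  helix <- generate_fixture(fixture_spec("helix", 20))$structure
  expect_gt(tm_score(pred$structure, helix), 0.95)
  unif <- predict_structure(toy_predictor(), pssm(matrix(0, 20, 20)),
                            predictor_config(ensemble_size = 1L))[[1]]
  expect_lt(mean(unif$plddt), 0.6)
})

test_that("toy predictions are deterministic and ensemble members differ", {
  p <- pssm(matrix(rnorm(20 * 20, sd = 2), 20, 20))
  a <- predict_structure(toy_predictor(), p)
  b <- predict_structure(toy_predictor(), p)
  expect_identical(a, b)
  expect_equal(length(a), 5L)
  expect_false(identical(ca_xyz(a[[1]]$structure), ca_xyz(a[[2]]$structure)))
  expect_equal(a[[1]]$ptm, mean(a[[1]]$plddt), tolerance = 1e-12)
})

test_that("recycles sharpen confidence without changing labels", {
  p <- pssm(matrix(rnorm(20 * 20, sd = 1.5), 20, 20))
  p0 <- predict_structure(toy_predictor(), p, predictor_config(n_recycles = 0L,
                                                               ensemble_size = 1L))[[1]]
  p3 <- predict_structure(toy_predictor(), p, predictor_config(n_recycles = 3L,
                                                               ensemble_size = 1L))[[1]]
  expect_gte(mean(p3$plddt), mean(p0$plddt))
  expect_equal(p3$labels, p0$labels)
})

test_that("toy distogram rows are normalized probability vectors", {
  pr <- predict_structure(toy_predictor(compute_distogram = TRUE),
                          strrep("A", 12),
                          predictor_config(ensemble_size = 1L))[[1]]
  d <- pr$distogram
  expect_equal(dim(d), c(12, 12, 64))
  sums <- apply(d, c(1, 2), sum)
  expect_equal(as.numeric(sums), rep(1, 144), tolerance = 1e-6)
})

test_that("ensemble gradient averages member gradients and matches the naive logit FD oracle", {
  fx <- generate_fixture(fixture_spec("helix_bundle", 30))
  tgt <- fx$structure
  p <- pssm_from_sequence(mutate_fraction(init_sequence_from_ss(fx$ss), 0.1, 3),
                          scale = 2)
  g1 <- ensemble_loss_gradient(p, tgt, cfg = predictor_config(ensemble_size = 1L))
  g_naive <- solufold:::.toy_member_grad_naive(p, tgt, loss_weights(), member = 1L)
  expect_lt(max(abs(g1 - g_naive)), 1e-6 * max(1, max(abs(g_naive))))
  # mean-of-members identity
  g5 <- ensemble_loss_gradient(p, tgt, cfg = predictor_config(ensemble_size = 5L))
  cache <- solufold:::.toy_target_cache(tgt)
  q <- pssm_decode(p)$probabilities
  members <- lapply(1:5, function(m)
    solufold:::cpp_member_grad(q, toy_propensity_table(m), cache$phi, cache$psi,
                               cache$ca, cache$true_bin, cache$use_ca,
                               as.numeric(loss_weights()), 8, 16, 0.75, -1, 1e-4))
  expect_equal(unname(g5), Reduce(`+`, members) / 5, tolerance = 1e-12)
})

test_that("toy loss decreases along the negative gradient for small steps", {
  fx <- generate_fixture(fixture_spec("helix_bundle", 30))
  tgt <- fx$structure
  cache <- solufold:::.toy_target_cache(tgt)
  w <- loss_weights()
  set.seed(7)
  ok <- 0L
  for (k in 1:20) {
    logits <- matrix(rnorm(30 * 20, sd = 1), 30, 20)
    p <- pssm(logits)
    g <- ensemble_loss_gradient(p, tgt, w, predictor_config(ensemble_size = 1L),
                                cache = cache)
    f0 <- solufold:::.toy_eval(pssm_decode(p)$probabilities, cache, w, 1)$total
    stepped <- pssm(unclass(p) - 1e-3 * g / max(abs(g)))
    f1 <- solufold:::.toy_eval(pssm_decode(stepped)$probabilities, cache, w, 1)$total
    if (f1 <= f0 + 1e-10) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("prediction respects the context chain and minimal length", {
  expect_error(predict_structure(toy_predictor(), strrep("A", 5)), "N >= 10")
  ctx <- generate_fixture(fixture_spec("helix", 12))$structure
  pr <- predict_structure(toy_predictor(), strrep("A", 15),
                          predictor_config(ensemble_size = 1L, context = ctx))[[1]]
  rt <- residue_table(pr$structure)
  expect_setequal(unique(rt$chain), c("A", "X"))
  expect_equal(sum(rt$chain == "X"), 12L)
})
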