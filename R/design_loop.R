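# Hallucination optimizer: initialization, ADAM updates on the PSSM,
# decoding, trajectories and soft starts.

#' Initialize a sequence from secondary structure
#'
#' Alanine for helix, valine for strand, glycine for loop, positionwise.
#'
#' @param ss String over {H,E,L}.
#' @return Sequence string.
#' @export
init_sequence_from_ss <- function(ss) {
  lab <- strsplit(ss, "")[[1]]
  if (!length(lab)) stop("empty secondary-structure string")
  map <- c(H = "A", E = "V", L = "G")
  out <- map[lab]
  if (anyNA(out)) stop("unknown secondary-structure label '",
                       lab[which(is.na(out))[1]], "'")
  paste(out, collapse = "")
}

#' Randomly mutate a fraction of positions
#'
#' Exactly `round(fraction * N)` positions (sampled without replacement) are
#' changed to a uniformly drawn *different* non-cysteine letter.
#' Deterministic given `rng_seed`.
#'
#' @param seq Sequence string.
#' @param fraction Fraction of positions to mutate, in [0, 1].
#' @param rng_seed Integer seed.
#' @return Mutated sequence string.
#' @export
mutate_fraction <- function(seq, fraction, rng_seed) {
  seq <- validate_sequence(seq)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- nchar(seq)
  k <- round(fraction * n)
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pool <- setdiff(aa_alphabet(), "C")
  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng))
  set.seed(as.integer(rng_seed))
  pos <- sample.int(n, k)
  for (i in pos) {
    choices <- setdiff(pool, chars[i])
    chars[i] <- choices[sample.int(length(choices), 1L)]
  }
  paste(chars, collapse = "")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' ADAM optimizer state
#'
#' @param n Sequence length (state matrices are n x 20).
#' @param lr Learning rate.
#' @param beta1,beta2 Moment decay rates in (0, 1).
#' @param eps Numerical stabilizer.
#' @return List of class `AdamState`.
#' @export
adam_state <- function(n, lr = 0.1, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, eps > 0)
  structure(list(m = matrix(0, n, 20), v = matrix(0, n, 20), t = 0L,
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "AdamState")
}

#' One ADAM update of a PSSM
#'
#' The gradient is first divided by its Frobenius norm (skipped if the norm
#' is below 1e-12), then a standard bias-corrected ADAM step is applied:
#' `logits <- logits - lr * m_hat / (sqrt(v_hat) + eps)`.
#'
#' @param p A [pssm].
#' @param grad N x 20 gradient matrix.
#' @param st An [adam_state].
#' @return List with updated `pssm` and `state`.
#' @export
adam_update <- function(p, grad, st) {
  stopifnot(inherits(st, "AdamState"))
  if (any(is.na(grad))) stop("NaN in gradient")
  logits <- unclass(p)
  if (!identical(dim(grad), dim(logits))) stop("gradient shape mismatch")
  fn <- sqrt(sum(grad^2))
  if (fn >= 1e-12) grad <- grad / fn
  st$t <- st$t + 1L
  st$m <- st$beta1 * st$m + (1 - st$beta1) * grad
  st$v <- st$beta2 * st$v + (1 - st$beta2) * grad^2
  m_hat <- st$m / (1 - st$beta1^st$t)
  v_hat <- st$v / (1 - st$beta2^st$t)
  logits <- logits - st$lr * m_hat / (sqrt(v_hat) + st$eps)
  list(pssm = pssm(logits), state = st)
}

#' Run one hallucination design trajectory
#'
#' Initializes the sequence from the target's secondary structure (A/V/G
#' encoding), mutates 10% of positions for diversity, then iterates:
#' ensemble loss gradient -> Frobenius-normalized ADAM update -> decode.
#' The trajectory converges when the decoded sequence's prediction reaches
#' `tm_min` TM-score to the target and `plddt_min` mean confidence; by
#' default iteration stops at convergence (set `stop_at_convergence = FALSE`
#' to always run `max_iter` rounds).
#'
#' @param target Target [Structure].
#' @param predictor A predictor (default [toy_predictor]).
#' @param w [loss_weights]; use `loss_weights(soft_start = TRUE)` with
#'   `init_sequence` for reseeded trajectories.
#' @param max_iter Maximum gradient-descent rounds (500 by default).
#' @param seed Integer seed (controls the initial mutations).
#' @param tm_min,plddt_min Convergence criteria (defaults mirror the
#'   downstream filter gates).
#' @param mutation_fraction Fraction of initial positions mutated.
#' @param init_sequence Optional explicit starting sequence (soft starts);
#'   when given, the secondary-structure initialization is skipped.
#' @param lr,beta1,beta2,eps ADAM hyperparameters.
#' @param init_scale Logit put on the starting letter of each position. The
#'   default +2 keeps the starting softmax close to one-hot while leaving the
#'   initial random mutations correctable before a misfold consolidates;
#'   larger values (e.g. +4) saturate the softmax and lower the convergence
#'   rate on the toy landscape.
#' @param stop_at_convergence Stop early once converged.
#' @return Object of class `DesignTrajectory`: data.frame `iterations`
#'   (iteration, sequence, loss components, tm, plddt), `final_sequence`,
#'   `converged`, `seed`.
#' @export
run_trajectory <- function(target, predictor = toy_predictor(),
                           w = loss_weights(), max_iter = 500L, seed = 1L,
                           tm_min = 0.8, plddt_min = 0.8,
                           mutation_fraction = 0.1, init_sequence = NULL,
                           lr = 0.1, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           init_scale = 2, stop_at_convergence = TRUE) {
  if (!inherits(predictor, "toy_predictor"))
    stop("only the toy predictor is runnable at desk scale; external ",
         "adapters implement predict_structure() and the same gradient contract")
  cache <- .toy_target_cache(target)
  ss <- assign_secondary_structure(target)
  seq0 <- if (is.null(init_sequence)) init_sequence_from_ss(ss) else
    validate_sequence(init_sequence)
  seq0 <- mutate_fraction(seq0, mutation_fraction, seed)
  p <- pssm_from_sequence(seq0, scale = init_scale)
  st <- adam_state(cache$n, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
  cfg <- predictor_config(n_recycles = 0L, ensemble_size = 5L)
  rows <- vector("list", max_iter)
  converged <- FALSE
  n_done <- 0L
  for (it in seq_len(max_iter)) {
    g <- tryCatch(
      ensemble_loss_gradient(p, target, w, cfg, cache = cache),
      error = function(e) stop("predictor failure at iteration ", it, ": ",
                               conditionMessage(e)))
    up <- adam_update(p, g, st)
    p <- up$pssm; st <- up$state
    dec <- pssm_decode(p)
    # per-iteration records are evaluated on the *decoded* sequence — the
    # argmax decode is what is carried forward and redesigned downstream
    q_dec <- .input_probs(dec$sequence)
    comps <- vapply(seq_len(cfg$ensemble_size), function(m) {
      b <- .toy_eval(q_dec, cache, w, m)
      c(b$l_fape, b$l_dist, b$l_plddt, b$l_ptm, b$total)
    }, numeric(5))
    cm <- rowMeans(comps)
    mean_plddt <- 1 - cm[3]
    pred1 <- predict_structure(predictor, dec$sequence, cfg)[[1]]
    tm <- tm_score(pred1$structure, target)
    rows[[it]] <- data.frame(
      iteration = it, sequence = dec$sequence,
      l_fape = cm[1], l_dist = cm[2], l_plddt = cm[3], l_ptm = cm[4],
      total = cm[5], tm = tm, plddt = mean_plddt, stringsAsFactors = FALSE)
    n_done <- it
    if (tm >= tm_min && mean_plddt >= plddt_min) {
      converged <- TRUE
      if (stop_at_convergence) break
    }
  }
  iters <- if (n_done > 0L) do.call(rbind, rows[seq_len(n_done)]) else
    data.frame(iteration = integer(0), sequence = character(0),
               l_fape = numeric(0), l_dist = numeric(0), l_plddt = numeric(0),
               l_ptm = numeric(0), total = numeric(0), tm = numeric(0),
               plddt = numeric(0))
  out <- list(iterations = iters,
              final_sequence = if (n_done > 0L) iters$sequence[n_done] else seq0,
              converged = converged, seed = as.integer(seed),
              target_length = cache$n)
  class(out) <- "DesignTrajectory"
  out
}

#' @export
print.DesignTrajectory <- function(x, ...) {
  n <- nrow(x$iterations)
  cat("DesignTrajectory: seed", x$seed, "-", n, "iterations,",
      if (x$converged) "converged" else "not converged", "\n")
  if (n > 0L) {
    last <- x$iterations[n, ]
    cat(sprintf("  final: loss %.4f, TM %.3f, mean pLDDT %.3f\n",
                last$total, last$tm, last$plddt))
    cat("  sequence:", x$final_sequence, "\n")
  }
  invisible(x)
}

#' @export
summary.DesignTrajectory <- function(object, ...) {
  it <- object$iterations
  structure(list(seed = object$seed, n_iter = nrow(it),
                 converged = object$converged,
                 final = if (nrow(it)) it[nrow(it), ] else NULL,
                 loss_range = if (nrow(it)) range(it$total) else c(NA, NA)),
            class = "summary.DesignTrajectory")
}

#' @export
print.summary.DesignTrajectory <- function(x, ...) {
  cat("Trajectory seed", x$seed, ":", x$n_iter, "iterations;",
      if (x$converged) "converged" else "not converged", "\n")
  if (!is.null(x$final))
    cat(sprintf("  loss %.4f -> %.4f; final TM %.3f, pLDDT %.3f\n",
                x$loss_range[2], x$loss_range[1], x$final$tm, x$final$plddt))
  invisible(x)
}

#' @export
plot.DesignTrajectory <- function(x, ...) {
  it <- x$iterations
  if (!nrow(it)) { warning("empty trajectory"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(it$iteration, it$total, type = "l", xlab = "iteration",
       ylab = "composite loss", main = "loss", ...)
  plot(it$iteration, it$tm, type = "l", ylim = c(0, 1), xlab = "iteration",
       ylab = "score", main = "TM (solid) / pLDDT (dashed)", ...)
  graphics::lines(it$iteration, it$plddt, lty = 2)
  invisible(x)
}

#' Draw soft-start seed sequences from converged trajectories
#'
#' Samples final sequences (uniformly, with replacement) from the converged
#' trajectories and mutates a fraction of positions. Callers must pair the
#' returned sequences with distogram-free weights
#' (`loss_weights(soft_start = TRUE)`).
#'
#' @param trajectories List of `DesignTrajectory` objects.
#' @param n Number of seed sequences to draw.
#' @param mutation_fraction Fraction of positions to mutate in each draw.
#' @param rng_seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
soft_start_seeds <- function(trajectories, n, mutation_fraction = 0.1,
                             rng_seed = 1L) {
  conv <- Filter(function(tr) isTRUE(tr$converged), trajectories)
  if (!length(conv)) stop("empty pool: no converged trajectory to reseed from")
  pool <- vapply(conv, function(tr) tr$final_sequence, character(1))
  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng))
  set.seed(as.integer(rng_seed))
  picks <- sample.int(length(pool), n, replace = TRUE)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  vapply(seq_len(n), function(i) {
    mutate_fraction(pool[picks[i]], mutation_fraction, sub_seeds[i])
  }, character(1))
}
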