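# End-to-end orchestration: configuration, staged pipeline, reporting.

# stable 32-bit FNV-1a hash of a string (stage-seed derivation, config hash)
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte (h may exceed .Machine$integer.max)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # (h * 16777619) mod 2^32 in two 16-bit pieces to stay exact in doubles
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

#' Derive a stage seed from the global seed
#'
#' Stable hash of (seed, stage name, index), kept below 2^31.
#'
#' @param global_seed Integer.
#' @param stage Stage name.
#' @param index Within-stage index.
#' @return Integer seed.
#' @export
derive_seed <- function(global_seed, stage, index = 1L) {
  as.integer(.fnv1a(paste(global_seed, stage, index, sep = "/")) %% 2147483647)
}

#' Pipeline run configuration
#'
#' @param target Either a file path to a structure or a [fixture_spec].
#' @param predictor `"toy"` (the only runnable choice at desk scale;
#'   `"external-adapter"` documents the plug-in point and errors at run time).
#' @param weights [loss_weights] for the initial trajectories.
#' @param n_trajectories Number of hallucination trajectories.
#' @param max_iter Gradient-descent rounds per trajectory.
#' @param n_soft_starts Reseeded (distogram-free) trajectories drawn from
#'   converged ones; 0 disables.
#' @param sampler `"uniform"` or `"burial"` mock inverse-folding sampler.
#' @param n_sequences Sequences sampled per designed backbone.
#' @param bias Sampling bias 20-vector (see [build_sampling_bias]).
#' @param fixed_positions Named letter vector or path to a fixed-position TSV.
#' @param criteria [filter_criteria].
#' @param blast_file Optional BLAST outfmt-6 file for sequence novelty.
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; all stage seeds derive from it.
#' @return Validated list of class `RunConfig`.
#' @export
run_config <- function(target, predictor = "toy", weights = loss_weights(),
                       n_trajectories = 3L, max_iter = 500L,
                       n_soft_starts = 0L, sampler = "uniform",
                       n_sequences = 2L, bias = numeric(20),
                       fixed_positions = character(0),
                       criteria = filter_criteria(), blast_file = NULL,
                       out_dir = tempfile("solufold_run_"), seed = 1L) {
  if (!predictor %in% c("toy", "external-adapter"))
    stop("predictor must be 'toy' or 'external-adapter'")
  if (!sampler %in% c("uniform", "burial"))
    stop("sampler must be 'uniform' or 'burial'")
  if (!inherits(criteria, "FilterCriteria"))
    stop("criteria must come from filter_criteria()")
  if (!inherits(weights, "LossWeights"))
    stop("weights must come from loss_weights()")
  if (n_trajectories < 1L) stop("n_trajectories must be >= 1")
  if (is.character(fixed_positions) && length(fixed_positions) == 1L &&
      is.null(names(fixed_positions)) && file.exists(fixed_positions))
    fixed_positions <- read_fixed_positions(fixed_positions)
  cfg <- list(target = target, predictor = predictor, weights = weights,
              n_trajectories = as.integer(n_trajectories),
              max_iter = as.integer(max_iter),
              n_soft_starts = as.integer(n_soft_starts), sampler = sampler,
              n_sequences = as.integer(n_sequences), bias = as.numeric(bias),
              fixed_positions = fixed_positions, criteria = criteria,
              blast_file = blast_file, out_dir = out_dir,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from JSON or YAML
#'
#' @param path Config file (`.json`, `.yaml`/`.yml`).
#' @return A validated [run_config].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  tgt <- raw$target
  if (is.list(tgt) && !is.null(tgt$kind))
    tgt <- fixture_spec(tgt$kind, tgt$n_res,
                        seed = tgt$seed %||% 1L,
                        loop_len = tgt$loop_len %||% 4L)
  crit <- if (is.null(raw$criteria)) filter_criteria() else
    do.call(filter_criteria, raw$criteria)
  w <- if (is.null(raw$weights)) loss_weights() else
    do.call(loss_weights, raw$weights)
  fixed <- raw$fixed_positions %||% character(0)
  if (is.list(fixed)) fixed <- unlist(fixed)
  run_config(target = tgt, predictor = raw$predictor %||% "toy", weights = w,
             n_trajectories = raw$n_trajectories %||% 3L,
             max_iter = raw$max_iter %||% 500L,
             n_soft_starts = raw$n_soft_starts %||% 0L,
             sampler = raw$sampler %||% "uniform",
             n_sequences = raw$n_sequences %||% 2L,
             bias = raw$bias %||% numeric(20),
             fixed_positions = fixed, criteria = crit,
             blast_file = raw$blast_file,
             out_dir = raw$out_dir %||% tempfile("solufold_run_"),
             seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(cfg) {
  canon <- cfg
  canon$out_dir <- NULL
  canon$target <- if (inherits(cfg$target, "FixtureSpec"))
    unclass(cfg$target) else as.character(cfg$target)
  h <- .fnv1a(paste(deparse(canon), collapse = ""))
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.load_target <- function(target) {
  if (inherits(target, "FixtureSpec")) generate_fixture(target)$structure
  else read_structure(target)
}

#' Run the full design pipeline
#'
#' Stages, in order: target preparation, hallucination trajectories,
#' optional soft starts, inverse-folding redesign (`n_sequences` per
#' converged backbone), reprediction scoring, filter gates, metrics report.
#' Every artifact is written under `cfg$out_dir` with the config hash and
#' stage seeds recorded; identical configurations produce byte-identical
#' reports.
#'
#' @param cfg A [run_config].
#' @param quiet Suppress stage messages.
#' @return Object of class `design_report` (also serialized to
#'   `report.tsv` / `summary.json` in `cfg$out_dir`).
#' @export
run_design_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (cfg$predictor != "toy")
    stop("stage 'setup': external predictor adapters are interface stubs; ",
         "only the toy predictor runs at desk scale")
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  pred <- toy_predictor()

  say("stage 1/6: target preparation")
  target <- .load_target(cfg$target)
  native_seq <- extract_sequence(target, permissive = TRUE)
  target_layers <- classify_layers(target)

  say("stage 2/6: hallucination trajectories (", cfg$n_trajectories, ")")
  trajs <- lapply(seq_len(cfg$n_trajectories), function(i) {
    run_trajectory(target, pred, w = cfg$weights, max_iter = cfg$max_iter,
                   seed = derive_seed(cfg$seed, "trajectory", i),
                   tm_min = cfg$criteria$tm_min,
                   plddt_min = cfg$criteria$plddt_min)
  })

  if (cfg$n_soft_starts > 0L && any(vapply(trajs, `[[`, logical(1), "converged"))) {
    say("stage 3/6: soft starts (", cfg$n_soft_starts, ")")
    seeds <- soft_start_seeds(trajs, cfg$n_soft_starts,
                              rng_seed = derive_seed(cfg$seed, "softstart", 1L))
    soft <- lapply(seq_along(seeds), function(i) {
      run_trajectory(target, pred, w = loss_weights(soft_start = TRUE),
                     max_iter = cfg$max_iter,
                     seed = derive_seed(cfg$seed, "softstart_traj", i),
                     tm_min = cfg$criteria$tm_min,
                     plddt_min = cfg$criteria$plddt_min,
                     init_sequence = seeds[i], mutation_fraction = 0)
    })
    trajs <- c(trajs, soft)
  } else say("stage 3/6: soft starts skipped")

  conv <- Filter(function(tr) tr$converged, trajs)
  say("stage 4/6: inverse-folding redesign (", length(conv), " backbones)")
  sampler <- if (cfg$sampler == "burial") mock_burial_sampler() else
    mock_uniform_sampler()
  designs <- list()
  for (i in seq_along(conv)) {
    backbone <- predict_structure(
      pred, conv[[i]]$final_sequence, predictor_config(n_recycles = 3L))[[1]]$structure
    seqs <- sample_sequences(backbone, sampler, sampler_options(
      n_sequences = cfg$n_sequences, bias = cfg$bias,
      fixed_positions = cfg$fixed_positions,
      rng_seed = derive_seed(cfg$seed, "sampler", i)))
    for (k in seq_along(seqs)) {
      designs[[length(designs) + 1L]] <- list(
        id = sprintf("traj%d_seq%d", i, k), sequence = seqs[k],
        source = sprintf("trajectory %d (seed %d)", i, conv[[i]]$seed))
    }
  }

  say("stage 5/6: reprediction scoring (", length(designs), " sequences)")
  evalues <- if (!is.null(cfg$blast_file))
    parse_blast_best_evalue(cfg$blast_file) else
    stats::setNames(numeric(0), character(0))
  records <- NULL
  for (d in designs) {
    ev <- if (d$id %in% names(evalues)) evalues[[d$id]] else NA_real_
    rec <- repredict_and_score(d$sequence, pred, target, id = d$id,
                               best_evalue = ev)
    predicted <- attr(rec, "predicted")
    pred_seq <- set_sequence(predicted, d$sequence)
    rec$surface_hydrophobic_fraction <- surface_hydrophobic_fraction(pred_seq)
    rec$recovery_total <- sequence_recovery(d$sequence, native_seq)
    rec$recovery_core <- {
      core <- which(target_layers == "core") - 1L
      if (length(core)) sequence_recovery(d$sequence, native_seq, core) else NA_real_
    }
    rec$recovery_surface <- {
      surf <- which(target_layers == "surface") - 1L
      if (length(surf)) sequence_recovery(d$sequence, native_seq, surf) else NA_real_
    }
    records <- rbind(records, as.data.frame(rec))
  }

  say("stage 6/6: filters and report")
  passed <- if (!is.null(records)) apply_filters(records, cfg$criteria) else NULL
  if (is.null(records))
    records <- data.frame(id = character(0), sequence = character(0),
                          tm_to_target = numeric(0), mean_plddt = numeric(0),
                          best_evalue = numeric(0), provenance = character(0),
                          surface_hydrophobic_fraction = numeric(0),
                          recovery_total = numeric(0), recovery_core = numeric(0),
                          recovery_surface = numeric(0))
  records$pass_tm <- records$tm_to_target > cfg$criteria$tm_min
  records$pass_plddt <- records$mean_plddt > cfg$criteria$plddt_min
  records$pass_evalue <- is.na(records$best_evalue) |
    records$best_evalue > cfg$criteria$evalue_min
  records$pass <- records$pass_tm & records$pass_plddt & records$pass_evalue

  report <- list(
    config_hash = hash, seed = cfg$seed,
    n_trajectories = length(trajs),
    n_converged = length(conv),
    records = records,
    summary = list(
      config_hash = hash, seed = cfg$seed,
      trajectories = length(trajs), converged = length(conv),
      scored = nrow(records), passed = sum(records$pass))
  )
  class(report) <- "design_report"
  write_report(records, file.path(cfg$out_dir, "report.tsv"))
  jsonlite::write_json(report$summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(conv))
    write_fasta(stats::setNames(
      vapply(conv, `[[`, character(1), "final_sequence"),
      paste0("backbone_traj", seq_along(conv))),
      file.path(cfg$out_dir, "backbones.fasta"))
  report
}

#' @export
print.design_report <- function(x, ...) {
  cat("design_report [config ", x$config_hash, ", seed ", x$seed, "]\n", sep = "")
  cat("  trajectories:", x$n_trajectories, "(", x$n_converged, "converged )\n")
  cat("  designs scored:", x$summary$scored, "; passed filters:",
      x$summary$passed, "\n")
  invisible(x)
}

#' Write a design report as TSV
#'
#' One row per design record with scores and per-gate pass flags; reparses
#' to identical records with [read_report].
#'
#' @param records data.frame of scored records.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
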