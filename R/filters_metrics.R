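# Reprediction scoring, filter gates, and analysis metrics.

#' Filter criteria for design selection
#'
#' Strict-inequality gates: a design passes when `tm > tm_min` AND
#' `plddt > plddt_min` AND `best_evalue > evalue_min`. Defaults are the
#' standard gates (0.80 / 0.80 / 0.1); structurally harder folds (rhomboid
#' protease class) use the 0.75 / 0.75 override.
#'
#' @param tm_min TM-score gate in (0, 1].
#' @param plddt_min Mean-confidence gate in [0, 1].
#' @param evalue_min Sequence-novelty gate (BLAST best e-value must exceed it).
#' @return List of class `FilterCriteria`.
#' @export
filter_criteria <- function(tm_min = 0.80, plddt_min = 0.80, evalue_min = 0.1) {
  if (tm_min <= 0 || tm_min > 1) stop("tm_min must be in (0, 1]")
  if (plddt_min < 0 || plddt_min > 1) stop("plddt_min must be in [0, 1]")
  if (evalue_min <= 0) stop("evalue_min must be positive")
  structure(list(tm_min = tm_min, plddt_min = plddt_min,
                 evalue_min = evalue_min), class = "FilterCriteria")
}

#' Repredict a designed sequence and score it against the target
#'
#' Repredicts with 3 recycles by default, fills the predicted structure
#' (ensemble member 1 by convention), TM-score to the target (index-wise
#' correspondence) and mean pLDDT. Force-field relaxation of the predicted
#' model is intentionally not performed; the record's provenance notes this.
#'
#' @param seq Designed sequence.
#' @param predictor A predictor object.
#' @param target Target [Structure] of the same length.
#' @param cfg [predictor_config] (default: 3 recycles, full ensemble).
#' @param id Record id.
#' @param best_evalue Optional BLAST best e-value for the sequence (NA =
#'   no hit found, treated as maximally novel).
#' @return One-row data.frame of class `DesignRecord`.
#' @export
repredict_and_score <- function(seq, predictor = toy_predictor(), target,
                                cfg = predictor_config(n_recycles = 3L),
                                id = "design", best_evalue = NA_real_) {
  seq <- validate_sequence(seq)
  if (nchar(seq) != n_residues(target))
    stop("sequence length (", nchar(seq), ") != target length (",
         n_residues(target), ")")
  preds <- predict_structure(predictor, seq, cfg)
  p1 <- preds[[1]]
  plddts <- vapply(preds, function(p) mean(p$plddt), numeric(1))
  rec <- data.frame(
    id = id, sequence = seq,
    tm_to_target = tm_score(p1$structure, target),
    mean_plddt = mean(plddts),
    best_evalue = best_evalue,
    provenance = "repredicted, 3-recycle config; relaxation skipped",
    stringsAsFactors = FALSE)
  attr(rec, "predicted") <- p1$structure
  class(rec) <- c("DesignRecord", class(rec))
  rec
}

#' Apply filter gates to scored design records
#'
#' Keeps records passing all three strict-inequality gates, preserving
#' order. Records with a missing e-value pass the novelty gate (no database
#' hit is maximal novelty) unless `strict_evalue = TRUE`.
#'
#' @param records data.frame of scored records (rows bind from
#'   [repredict_and_score]).
#' @param c A [filter_criteria].
#' @param strict_evalue Reject records lacking an e-value.
#' @return The passing subset of `records`.
#' @export
apply_filters <- function(records, c = filter_criteria(),
                          strict_evalue = FALSE) {
  if (!nrow(records)) return(records)
  ev <- records$best_evalue
  ev_ok <- ifelse(is.na(ev), !strict_evalue, ev > c$evalue_min)
  keep <- records$tm_to_target > c$tm_min &
    records$mean_plddt > c$plddt_min & ev_ok
  records[keep, , drop = FALSE]
}

#' Sequence recovery
#'
#' Percentage of positions whose residue matches the reference, optionally
#' restricted to a 0-based index subset (the denominator is then the subset
#' size).
#'
#' @param design,reference Equal-length sequences.
#' @param subset Optional integer vector of 0-based positions.
#' @return Percentage in [0, 100].
#' @export
sequence_recovery <- function(design, reference, subset = NULL) {
  design <- validate_sequence(design)
  reference <- validate_sequence(reference)
  if (nchar(design) != nchar(reference)) stop("sequence length mismatch")
  d <- strsplit(design, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (any(subset < 0L | subset >= length(d))) stop("subset index out of range")
    d <- d[subset + 1L]; r <- r[subset + 1L]
  }
  100 * sum(d == r) / length(d)
}

#' Classify residues into core / boundary / surface layers
#'
#' Core: SASA < 20 Angstrom^2; surface: SASA > 40; boundary between.
#'
#' @param s A [Structure].
#' @param sasa Optional precomputed per-residue SASA.
#' @return Character vector over {core, boundary, surface}, one per residue.
#' @export
classify_layers <- function(s, sasa = NULL) {
  if (is.null(sasa)) sasa <- sasa_per_residue(s)
  ifelse(sasa < 20, "core", ifelse(sasa > 40, "surface", "boundary"))
}

#' Fraction of hydrophobic residues on the surface
#'
#' Surface residues are those with SASA > 40 Angstrom^2; the apolar set is
#' exactly `GPAVILMFYW`.
#'
#' @param s A [Structure].
#' @param sasa Optional precomputed per-residue SASA.
#' @return Fraction in [0, 1].
#' @export
surface_hydrophobic_fraction <- function(s, sasa = NULL) {
  if (is.null(sasa)) sasa <- sasa_per_residue(s)
  surface <- as.numeric(sasa) > 40
  if (!any(surface)) stop("undefined: structure has no surface residues")
  seq <- extract_sequence(s, chain = NULL, permissive = TRUE)
  # multi-chain: concatenate all chains in order
  rt <- residue_table(s)
  if (length(unique(rt$chain)) > 1L) {
    seq <- paste(vapply(unique(rt$chain), function(ch)
      extract_sequence(s, ch, permissive = TRUE), character(1)), collapse = "")
  }
  chars <- strsplit(seq, "")[[1]]
  mean(chars[surface] %in% aa_apolar())
}

#' Secondary-structure contact order
#'
#' Contacts are residue pairs (i, j) with Ca distance at most `cutoff`,
#' sequence separation `|i - j| >= min_separation`, and i, j in *different*
#' secondary-structure elements (distinct segments of the DSSP-style
#' assignment). Returns the mean sequence separation over contacts and its
#' length-normalized (relative) value.
#'
#' @param s A [Structure].
#' @param cutoff Contact distance cutoff (Angstrom).
#' @param min_separation Minimum sequence separation ("more than four
#'   residues apart" = 5).
#' @param ss Optional secondary-structure string (default: computed).
#' @return List: `mean_separation`, `relative`, `n_contacts`, and
#'   `no_contacts` flag (mean defined 0 when no pair qualifies).
#' @export
ss_contact_order <- function(s, cutoff = 8, min_separation = 5L, ss = NULL) {
  if (is.null(ss)) ss <- assign_secondary_structure(s)
  seg <- ss_segments(ss)
  ca <- ca_xyz(s)
  n <- nrow(ca)
  if (nchar(ss) != n) stop("secondary-structure string length mismatch")
  d <- as.matrix(stats::dist(ca))
  seps <- integer(0)
  for (i in seq_len(n - 1L)) {
    js <- seq(i + 1L, n)
    ok <- d[i, js] <= cutoff & (js - i) >= min_separation & seg[js] != seg[i]
    seps <- c(seps, (js - i)[ok])
  }
  if (!length(seps))
    return(list(mean_separation = 0, relative = 0, n_contacts = 0L,
                no_contacts = TRUE))
  list(mean_separation = mean(seps), relative = mean(seps) / n,
       n_contacts = length(seps), no_contacts = FALSE)
}

#' Best (minimum) e-value per query from BLAST tabular output
#'
#' Parses 12-column outfmt-6 TSV; e-value is column 11. Queries with no hits
#' are absent from the mapping (downstream they are treated as maximally
#' novel).
#'
#' @param path BLAST outfmt-6 file path.
#' @return Named numeric vector: query id -> minimum e-value.
#' @export
parse_blast_best_evalue <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  out <- new.env()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("malformed BLAST line ", k, ": expected 12 tab-separated fields, got ",
           length(f))
    ev <- suppressWarnings(as.numeric(f[11]))
    if (is.na(ev)) stop("malformed BLAST line ", k, ": e-value '", f[11], "'")
    q <- f[1]
    cur <- mget(q, envir = out, ifnotfound = list(Inf))[[1]]
    assign(q, min(cur, ev), envir = out)
  }
  vals <- mget(ls(out), envir = out)
  stats::setNames(as.numeric(vals), names(vals))
}
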