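# Epitope transplantation from a natural donor onto a designed scaffold.

#' Build an epitope residue map between donor and scaffold
#'
#' Computes the TM-score of the donor onto the scaffold over the supplied
#' correspondence (normalized by scaffold length) and returns the map
#' restricted to the epitope residues. Maps with TM <= 0.7 carry a
#' below-threshold warning flag — the screening gate used when shortlisting
#' structurally compatible scaffolds.
#'
#' @param scaffold,donor [Structure] objects.
#' @param corr [correspondence] of (donor index, scaffold index) pairs
#'   covering at least the epitope.
#' @param epitope Integer vector of 0-based donor residue indices.
#' @return List of class `EpitopeMap`: `pairs` (donor, scaffold index
#'   matrix), `superposition_tm`, `below_threshold`.
#' @export
build_epitope_map <- function(scaffold, donor, corr, epitope) {
  epitope <- as.integer(epitope)
  missing_ep <- setdiff(epitope, corr[, 1])
  if (length(missing_ep))
    stop("epitope index ", missing_ep[1], " is not covered by the correspondence")
  tm <- tm_score(donor, scaffold, corr, norm_length = n_residues(scaffold))
  keep <- corr[, 1] %in% epitope
  m <- list(pairs = cbind(donor = corr[keep, 1], scaffold = corr[keep, 2]),
            superposition_tm = tm, below_threshold = tm <= 0.7)
  class(m) <- "EpitopeMap"
  if (m$below_threshold)
    warning(sprintf("scaffold/donor TM %.3f <= 0.7: epitope environment may not be preserved", tm))
  m
}

#' @export
print.EpitopeMap <- function(x, ...) {
  cat(sprintf("EpitopeMap: %d residue pairs, superposition TM %.3f%s\n",
              nrow(x$pairs), x$superposition_tm,
              if (x$below_threshold) " (below 0.7 gate)" else ""))
  invisible(x)
}

#' Transplant an epitope sequence onto a scaffold
#'
#' Returns the scaffold sequence with position `j` carrying the donor letter
#' at `i` for every (i, j) pair of the map; the length is unchanged.
#'
#' @param scaffold_seq,donor_seq Sequences.
#' @param m An [build_epitope_map] result.
#' @return Chimeric sequence string.
#' @export
transplant_sequence <- function(scaffold_seq, donor_seq, m) {
  scaffold_seq <- validate_sequence(scaffold_seq)
  donor_seq <- validate_sequence(donor_seq)
  if (!nrow(m$pairs)) return(scaffold_seq)
  di <- m$pairs[, "donor"]; si <- m$pairs[, "scaffold"]
  if (any(di < 0L | di >= nchar(donor_seq))) stop("donor index out of range")
  if (any(si < 0L | si >= nchar(scaffold_seq))) stop("scaffold index out of range")
  sc <- strsplit(scaffold_seq, "")[[1]]
  dn <- strsplit(donor_seq, "")[[1]]
  sc[si + 1L] <- dn[di + 1L]
  paste(sc, collapse = "")
}

#' Screen chimeric sequences by reprediction
#'
#' Repredicts each chimera (3-recycle configuration), keeps those with mean
#' pLDDT above `plddt_min` and TM-score to the starting scaffold above
#' `tm_min`, and reports all scores.
#'
#' @param chimeras Character vector of sequences.
#' @param predictor A predictor object.
#' @param scaffold Scaffold [Structure] (reference for the TM gate).
#' @param plddt_min Confidence gate (default 0.90).
#' @param tm_min TM gate.
#' @return List with `scores` (data.frame over all chimeras, with `pass`)
#'   and `passing` (the passing subset of sequences).
#' @export
screen_chimeras <- function(chimeras, predictor = toy_predictor(), scaffold,
                            plddt_min = 0.90, tm_min = 0.8) {
  if (!length(chimeras))
    return(list(scores = data.frame(sequence = character(0), tm = numeric(0),
                                    plddt = numeric(0), pass = logical(0)),
                passing = character(0)))
  cfg <- predictor_config(n_recycles = 3L)
  rows <- lapply(chimeras, function(sq) {
    rec <- repredict_and_score(sq, predictor, scaffold, cfg)
    data.frame(sequence = sq, tm = rec$tm_to_target, plddt = rec$mean_plddt,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  scores$pass <- scores$plddt > plddt_min & scores$tm > tm_min
  list(scores = scores, passing = scores$sequence[scores$pass])
}

#' Parse a Foldseek tabular hit file
#'
#' Reads the default Foldseek TSV (query, target, then alignment columns,
#' with an alignment TM-score column when requested in the output format)
#' and returns the hits, best first, with the TM gate applied.
#'
#' @param path Foldseek hit file path.
#' @param tm_column 1-based column index holding the TM-score.
#' @param tm_min Keep hits with TM above this (default 0.7, the scaffold
#'   compatibility gate).
#' @return data.frame with `query`, `target`, `tm`.
#' @export
parse_foldseek_hits <- function(path, tm_column = 3L, tm_min = 0.7) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(query = character(0), target = character(0),
                      tm = numeric(0)))
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < tm_column)
      stop("malformed Foldseek line ", k, ": fewer than ", tm_column, " fields")
    tm <- suppressWarnings(as.numeric(f[tm_column]))
    if (is.na(tm)) stop("malformed Foldseek line ", k, ": TM '", f[tm_column], "'")
    data.frame(query = f[1], target = f[2], tm = tm, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$tm > tm_min, , drop = FALSE]
  df[order(-df$tm), , drop = FALSE]
}

#' Read an epitope definition TSV
#'
#' Columns `donor_index` and `scaffold_index` (0-based).
#'
#' @param path TSV path.
#' @return List with `corr` ([correspondence]) and `epitope` (donor indices).
#' @export
read_epitope_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("donor_index", "scaffold_index") %in% names(df)))
    stop("epitope file needs columns donor_index, scaffold_index")
  list(corr = correspondence(df$donor_index, df$scaffold_index),
       epitope = as.integer(df$donor_index))
}
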