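#' Macromolecular structure container
#'
#' A `Structure` is a light S3 wrapper around an atom table with one row per
#' atom and columns `chain`, `resno` (author numbering), `resname` (3-letter
#' code), `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom). Residues
#' are kept in file order within each chain; all downstream math addresses
#' residues by 0-based contiguous index per chain, author numbering is
#' retained only for I/O.
#'
#' @param atoms data.frame with the columns listed above.
#' @return Object of class `Structure`.
#' @export
Structure <- function(atoms) {
  req <- c("chain", "resno", "resname", "elety", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no protein atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$elety <- as.character(atoms$elety)
  atoms$element <- toupper(as.character(atoms$element))
  rownames(atoms) <- NULL
  s <- list(atoms = atoms)
  class(s) <- "Structure"
  s
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("Structure:", length(unique(rt$chain)), "chain(s),",
      nrow(rt), "residues,", nrow(x$atoms), "atoms\n")
  for (ch in unique(rt$chain)) {
    n <- sum(rt$chain == ch)
    cat("  chain", ch, ":", n, "residues\n")
  }
  invisible(x)
}

#' Residue table of a Structure
#'
#' One row per residue in order, with 0-based per-chain index.
#'
#' @param s Structure.
#' @param chain Optional chain id to restrict to.
#' @return data.frame with columns `chain`, `resno`, `resname`, `index`.
#' @export
residue_table <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) {
    a <- a[a$chain == chain, , drop = FALSE]
    if (nrow(a) == 0L) stop("no such chain: ", chain)
  }
  key <- paste(a$chain, a$resno, sep = "\r")
  first <- !duplicated(key)
  rt <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   resname = a$resname[first], stringsAsFactors = FALSE)
  rt$index <- stats::ave(seq_len(nrow(rt)), rt$chain, FUN = seq_along) - 1L
  rt
}

#' Number of residues
#' @param s Structure.
#' @param chain Optional chain id.
#' @return Integer count.
#' @export
n_residues <- function(s, chain = NULL) nrow(residue_table(s, chain))

# N x 3 matrix of coordinates of one named atom per residue (NA rows where absent)
atom_xyz <- function(s, elety = "CA", chain = NULL) {
  rt <- residue_table(s, chain)
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  a <- a[a$elety == elety, , drop = FALSE]
  m <- matrix(NA_real_, nrow(rt), 3)
  key_rt <- paste(rt$chain, rt$resno, sep = "\r")
  key_a <- paste(a$chain, a$resno, sep = "\r")
  hit <- match(key_rt, key_a)
  ok <- !is.na(hit)
  m[ok, ] <- as.matrix(a[hit[ok], c("x", "y", "z")])
  m
}

#' Ca coordinates
#' @param s Structure.
#' @param chain Optional chain id.
#' @return N x 3 numeric matrix (NA rows where a residue lacks a Ca atom).
#' @export
ca_xyz <- function(s, chain = NULL) atom_xyz(s, "CA", chain)

# apply a function to the coordinate block, returning a new Structure
transform_coords <- function(s, f) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- f(xyz)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

.guess_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
}

.is_hydrogen <- function(element, elety) {
  element %in% c("H", "D") |
    (element == "" & grepl("^[0-9]*[HD]", elety))
}

# altloc resolution: per (chain,resno,elety) keep highest occupancy, tie -> "A"
# (ties broken by alphabetically first altloc id)
.resolve_altloc <- function(df) {
  alt <- df$alt
  alt[is.na(alt)] <- ""
  occ <- df$occ
  occ[is.na(occ)] <- 1
  key <- paste(df$chain, df$resno, df$elety, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  ord <- order(key, -occ, alt)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  df <- df[!duplicated(key), , drop = FALSE]
  # restore original file order
  df[order(df$.row), , drop = FALSE]
}

#' Read a macromolecular structure
#'
#' Reads PDB (via bio3d) or mmCIF (built-in `atom_site` loop parser) into a
#' [Structure]. Waters and hetero groups are excluded, hydrogens are dropped,
#' and alternate locations are resolved to the highest-occupancy conformer
#' (ties to altloc "A"). Only the first model of multi-model files is used.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @param keep_hetero Keep non-water HETATM records (default FALSE).
#' @return A [Structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- .guess_format(path, format)
  df <- if (format == "pdb") .read_pdb_atoms(path) else .read_mmcif_atoms(path)
  df$.row <- seq_len(nrow(df))
  if (!keep_hetero) df <- df[df$type == "ATOM", , drop = FALSE]
  df <- df[df$resname != "HOH", , drop = FALSE]
  df <- df[!.is_hydrogen(df$element, df$elety), , drop = FALSE]
  df <- df[df$resname %in% names(.aa321_permissive), , drop = FALSE]
  if (nrow(df) == 0L) stop("empty structure: no protein residues in ", path)
  df <- .resolve_altloc(df)
  Structure(df[, c("chain", "resno", "resname", "elety", "element", "x", "y", "z")])
}

.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  elem <- a$elesy
  elem[is.na(elem)] <- ""
  # infer element from atom name when the element column is blank
  blank <- elem == ""
  elem[blank] <- sub("^[0-9]*", "", a$elety[blank])
  elem[blank] <- substr(elem[blank], 1, 1)
  data.frame(type = a$type, chain = ifelse(is.na(a$chain), "A", a$chain),
             resno = a$resno, resname = a$resid, elety = a$elety,
             element = toupper(elem), alt = a$alt, occ = a$o,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

# minimal tokenizer for one mmCIF data row (handles ' and " quoting)
.cif_tokens <- function(line) {
  out <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  loop_at <- grep("^\\s*loop_\\s*$", lines)
  start <- NA_integer_
  for (la in loop_at) {
    k <- la + 1L
    if (k <= length(lines) && grepl("^_atom_site\\.", trimws(lines[k]))) { start <- la; break }
  }
  if (is.na(start)) stop("mmCIF parse error in ", path, ": no _atom_site loop found")
  k <- start + 1L
  cols <- character(0)
  while (k <= length(lines) && grepl("^_atom_site\\.", trimws(lines[k]))) {
    cols <- c(cols, sub("^_atom_site\\.", "", trimws(lines[k])))
    k <- k + 1L
  }
  rows <- list()
  while (k <= length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
    tok <- .cif_tokens(lines[k])
    if (length(tok) != length(cols))
      stop("mmCIF parse error in ", path, " at line ", k,
           ": expected ", length(cols), " fields, got ", length(tok))
    rows[[length(rows) + 1L]] <- tok
    k <- k + 1L
  }
  if (!length(rows)) stop("empty structure: no atom_site rows in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% cols) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  model <- pick("pdbx_PDB_model_num")
  keep <- if (all(is.na(model))) rep(TRUE, nrow(m)) else model == model[1]
  alt <- pick("label_alt_id")
  alt[alt %in% c(".", "?")] <- ""
  occ <- suppressWarnings(as.numeric(pick("occupancy")))
  df <- data.frame(
    type = pick("group_PDB"),
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id"))),
    resname = pick("auth_comp_id", "label_comp_id"),
    elety = pick("auth_atom_id", "label_atom_id"),
    element = pick("type_symbol"),
    alt = alt, occ = occ,
    x = suppressWarnings(as.numeric(pick("Cartn_x"))),
    y = suppressWarnings(as.numeric(pick("Cartn_y"))),
    z = suppressWarnings(as.numeric(pick("Cartn_z"))),
    stringsAsFactors = FALSE
  )
  df[keep, , drop = FALSE]
}

#' Write a macromolecular structure
#'
#' Writes PDB (ATOM/TER/END records) or mmCIF (`atom_site` loop). PDB author
#' numbering is limited to 9999; larger residue numbers are an error in the
#' PDB dialect (use mmCIF for long chains).
#'
#' @param s A [Structure].
#' @param path Output file path.
#' @param format `"pdb"` or `"mmcif"` (default by extension, falling back to pdb).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(s, "Structure"))
  format <- .guess_format(path, match.arg(format))
  a <- s$atoms
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("non-finite coordinates; refusing to write")
  if (format == "pdb") {
    if (any(a$resno > 9999L) || any(a$resno < -999L))
      stop("residue number out of PDB range (|resno| > 9999); write mmCIF instead")
    .write_pdb_atoms(a, path)
  } else {
    .write_mmcif_atoms(a, path)
  }
  invisible(path)
}

.write_pdb_atoms <- function(a, path) {
  con <- file(path, "w")
  on.exit(close(con))
  eleno <- 0L
  chains <- unique(a$chain)
  for (ch in chains) {
    b <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(b))) {
      eleno <- eleno + 1L
      name <- b$elety[i]
      # atom-name column convention: right-pad 1-char elements into cols 14-16
      name_fmt <- if (nchar(name) < 4 && nchar(b$element[i]) == 1)
        sprintf(" %-3s", name) else sprintf("%-4s", name)
      writeLines(sprintf(
        "ATOM  %5d %s%s%3s %1s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        eleno %% 100000L, name_fmt, " ", b$resname[i], ch, b$resno[i], " ",
        b$x[i], b$y[i], b$z[i], 1.0, 0.0, b$element[i]), con)
    }
    writeLines(sprintf("TER   %5d      %3s %1s%4d",
                       (eleno + 1L) %% 100000L,
                       b$resname[nrow(b)], ch, b$resno[nrow(b)]), con)
    eleno <- eleno + 1L
  }
  writeLines("END", con)
}

.write_mmcif_atoms <- function(a, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_solufold", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.label_alt_id",
               "_atom_site.occupancy",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z"),
             con)
  writeLines(sprintf("ATOM %d %s %s %s %s %d . 1.00 %.3f %.3f %.3f",
                     seq_len(nrow(a)), a$element, a$elety, a$resname,
                     a$chain, a$resno, a$x, a$y, a$z), con)
  writeLines("#", con)
}

#' Extract the one-letter sequence of a chain
#'
#' @param s A [Structure].
#' @param chain Chain id (default: first chain).
#' @param permissive Map common modified residues to their parent (e.g. MSE
#'   to M) instead of erroring.
#' @return Character scalar sequence.
#' @export
extract_sequence <- function(s, chain = NULL, permissive = FALSE) {
  rt <- residue_table(s)
  if (is.null(chain)) chain <- rt$chain[1]
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0L) stop("no such chain: ", chain)
  map <- if (permissive) .aa321_permissive else .aa321
  letters1 <- map[rt$resname]
  if (anyNA(letters1)) {
    bad <- rt$resname[which(is.na(letters1))[1]]
    stop("unknown residue name '", bad, "'",
         if (!permissive) " (set permissive = TRUE for modified residues)"
         else " (no canonical parent; X is outside the design alphabet)")
  }
  paste(letters1, collapse = "")
}

#' Replace the sequence of a single-chain Structure
#'
#' Keeps the backbone unchanged and rebuilds the per-residue side-chain
#' representation (CB and the pseudo side-chain centroid) to match the new
#' residue identities. Used by the mock inverse-folding stage to evaluate a
#' redesigned sequence on a fixed backbone.
#'
#' @param s A single-chain [Structure] with backbone N, CA, C atoms.
#' @param seq New sequence, same length as the chain.
#' @return A [Structure].
#' @export
set_sequence <- function(s, seq) {
  seq <- validate_sequence(seq)
  rt <- residue_table(s)
  if (length(unique(rt$chain)) != 1L) stop("set_sequence expects a single chain")
  if (nchar(seq) != nrow(rt)) stop("sequence length != residue count")
  n <- atom_xyz(s, "N"); ca <- atom_xyz(s, "CA"); cc <- atom_xyz(s, "C")
  o <- atom_xyz(s, "O")
  if (anyNA(n) || anyNA(ca) || anyNA(cc)) stop("backbone N/CA/C required")
  build_structure_from_backbone(n, ca, cc, o, seq, chain = rt$chain[1])
}

#' Read sequences from a FASTA file
#'
#' One record per header; whitespace stripped, lower case normalized to
#' upper case, alphabet validated against the 20 canonical letters.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) {
    if (all(trimws(lines) == "")) return(stats::setNames(character(0), character(0)))
    stop("not a FASTA file (no '>' header): ", path)
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[setdiff(seq(hdr[i] + 1L, ends[i]), integer(0))]
    if (hdr[i] + 1L > ends[i]) body <- character(0)
    gsub("\\s", "", paste(body, collapse = ""))
  }, character(1))
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- which(!chars %in% aa_alphabet())
    if (length(bad))
      stop("FASTA record '", ids[i], "': illegal character '",
           chars[bad[1]], "' at position ", bad[1])
    if (!nchar(seqs[i])) stop("FASTA record '", ids[i], "' is empty")
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
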