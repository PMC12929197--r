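#' Parse PDB-format text into an atom table
#'
#' Reads `ATOM`/`HETATM` records from PDB-dialect text and returns one row per
#' atom.  `MODEL`/`ENDMDL` blocks are honoured (atoms outside any block belong
#' to model 1); alternate locations are resolved by keeping the first
#' occurrence of each atom; hydrogens are dropped, since docking models are
#' heavy-atom only.  A missing element column is inferred from the atom-name
#' field using the standard PDB alignment rule (two-character element symbols
#' start in column 13).
#'
#' @param pdb_text PDB text: a single string or a character vector of lines.
#' @return A data frame with columns `record`, `serial`, `name`, `resname`,
#'   `chain`, `resno`, `icode`, `x`, `y`, `z`, `element`, `model`.
#'   Coordinates are in angstroms.
#' @examples
#' txt <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  ALA A   2      10.000   0.000   0.000  1.00  0.00           C")
#' parse_structure(txt)
#' @seealso [write_structure()], [find_cofactors()]
#' @export
parse_structure <- function(pdb_text) {
  if (length(pdb_text) == 0L || all(!nzchar(pdb_text)))
    stop("empty PDB input")
  lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in input")

  # model bookkeeping: running model index, 1 if no MODEL blocks
  model_of <- integer(length(lines))
  cur <- 1L; seen_model <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") { cur <- if (seen_model) cur + 1L else 1L; seen_model <- TRUE }
    model_of[i] <- cur
  }

  idx <- which(is_atom)
  ln <- lines[idx]
  num_field <- function(s, a, b, what) {
    raw <- trimws(substr(s, a, b))
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!nzchar(raw) | is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, idx[bad[1L]], trimws(ln[bad[1L]])))
    v
  }
  atoms <- data.frame(
    record  = trimws(substr(ln, 1L, 6L)),
    serial  = as.integer(num_field(ln, 7L, 11L, "serial")),
    name    = trimws(substr(ln, 13L, 16L)),
    altloc  = substr(ln, 17L, 17L),
    resname = trimws(substr(ln, 18L, 20L)),
    chain   = substr(ln, 22L, 22L),
    resno   = as.integer(num_field(ln, 23L, 26L, "residue number")),
    icode   = substr(ln, 27L, 27L),
    x       = num_field(ln, 31L, 38L, "x coordinate"),
    y       = num_field(ln, 39L, 46L, "y coordinate"),
    z       = num_field(ln, 47L, 54L, "z coordinate"),
    element = trimws(substr(ln, 77L, 78L)),
    model   = model_of[idx],
    stringsAsFactors = FALSE)

  blank <- !nzchar(atoms$element)
  if (any(blank))
    atoms$element[blank] <- infer_element(substr(ln[blank], 13L, 16L))

  # first altloc wins
  key <- paste(atoms$model, atoms$chain, atoms$resno, atoms$icode, atoms$name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}

# PDB alignment rule: names occupying column 13 start with a two-letter
# element ("FE1 "); one-letter elements are indented (" NZ ").
infer_element <- function(name_field) {
  first <- substr(name_field, 1L, 1L)
  two <- first != " " & !grepl("^[0-9]", first)
  nm <- gsub("[^A-Za-z]", "", trimws(name_field))
  ifelse(two, toupper(substr(nm, 1L, 2L)), toupper(substr(nm, 1L, 1L)))
}

#' Write an atom table as PDB-format text
#'
#' Emits fixed-width `ATOM`/`HETATM` records (coordinates to three decimals),
#' `TER` records between chains, `MODEL`/`ENDMDL` blocks when more than one
#' model is present, and a terminating `END`.  Output is re-parseable by
#' [parse_structure()] with all fields preserved.
#'
#' @param atoms atom table as produced by [parse_structure()]; a `record`
#'   column is optional (residues with non-standard names default to HETATM).
#' @return A single string of PDB text.
#' @export
write_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (any(abs(c(atoms$x, atoms$y, atoms$z)) >= 10000))
    stop("coordinate overflows fixed-width PDB field")
  if (is.null(atoms$record))
    atoms$record <- ifelse(atoms$resname %in% AA3, "ATOM", "HETATM")
  if (is.null(atoms$model)) atoms$model <- 1L
  if (is.null(atoms$icode)) atoms$icode <- " "

  fmt_one <- function(a) {
    # element-aligned atom-name field
    nm <- a$name
    pad <- ifelse(nchar(a$element) >= 2L | nchar(nm) >= 4L,
                  formatC(nm, width = -4L),
                  paste0(" ", formatC(nm, width = -3L)))
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record, a$serial, pad, " ", a$resname, a$chain, a$resno,
            a$icode, a$x, a$y, a$z, 1, 0, a$element)
  }
  out <- character(0)
  models <- sort(unique(atoms$model))
  for (m in models) {
    sub <- atoms[atoms$model == m, , drop = FALSE]
    if (length(models) > 1L) out <- c(out, sprintf("MODEL %8d", m))
    chains <- unique(sub$chain)
    for (ch in chains) {
      cs <- sub[sub$chain == ch, , drop = FALSE]
      out <- c(out, vapply(seq_len(nrow(cs)),
                           function(i) fmt_one(cs[i, , drop = FALSE]), ""))
      last <- cs[nrow(cs), , drop = FALSE]
      if (last$record == "ATOM")
        out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                              last$serial + 1L, last$resname, last$chain,
                              last$resno))
    }
    if (length(models) > 1L) out <- c(out, "ENDMDL")
  }
  paste0(paste(c(out, "END"), collapse = "\n"), "\n")
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
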