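#' Recognised redox-cofactor HET codes
#'
#' Maps PDB heteroatom residue codes to cofactor kinds: `SF4` (cubane
#' \[4Fe-4S\] cluster), `FES` (\[2Fe-2S\] cluster), `F3S` (\[3Fe-4S\]
#' cluster) and `FMN` (flavin mononucleotide).
#' @keywords internal
COFACTOR_KINDS <- c(SF4 = "FE4S4", FES = "FE2S2", F3S = "FE3S4", FMN = "FMN")

# expected iron stoichiometry per FeS kind
FE_COUNT <- c(FE4S4 = 4L, FE2S2 = 2L, FE3S4 = 3L)

#' The 14 ring atoms of the isoalloxazine system.  The conjugated tricyclic
#' ring is the electron conduit of FMN; carbonyl oxygens, ring methyls and
#' the ribityl-phosphate tail are excluded from the edge set.
#' @keywords internal
FMN_RING_ATOMS <- c("N1", "C2", "N3", "C4", "C4A", "N5", "C5A",
                    "C6", "C7", "C8", "C9", "C9A", "N10", "C10")

#' Detect redox cofactors in a parsed structure
#'
#' Scans HETATM residues for recognised electron-carrying prosthetic groups
#' and returns one cofactor object per hit, with its designated edge-atom set
#' populated.  For FeS clusters the edge atoms are the Fe atoms (the atoms
#' between which edge-to-edge distances are measured); `edge_policy =
#' "fe_and_s"` additionally includes the inorganic sulfurs.  For FMN the edge
#' atoms are the 14 isoalloxazine ring atoms.  Unrecognised HET residues
#' (other than water) are skipped with a warning.
#'
#' @param atoms atom table from [parse_structure()].
#' @param edge_policy `"fe_only"` (default) or `"fe_and_s"`; applies to FeS
#'   clusters only.
#' @return A list of `redox_cofactor` objects, each with elements `kind`,
#'   `resname`, `atoms`, `edge_atoms`, `chain`, `resno`, `model`.
#' @examples
#' cpx <- make_toy_complex(complex_spec(target_R = 9, seed = 1))
#' cofs <- find_cofactors(parse_structure(cpx$pdb))
#' vapply(cofs, function(co) co$kind, "")
#' @export
find_cofactors <- function(atoms, edge_policy = c("fe_only", "fe_and_s")) {
  edge_policy <- match.arg(edge_policy)
  het <- atoms[atoms$record == "HETATM", , drop = FALSE]
  if (nrow(het) == 0L) return(list())
  key <- paste(het$model, het$chain, het$resno, het$resname, sep = "\r")
  groups <- split(seq_len(nrow(het)), key)
  # preserve file order of residues
  groups <- groups[order(vapply(groups, min, 0L))]

  out <- list()
  unknown <- character(0)
  for (g in groups) {
    res <- het[g, , drop = FALSE]
    code <- res$resname[1L]
    if (!code %in% names(COFACTOR_KINDS)) {
      if (!code %in% c("HOH", "WAT")) unknown <- c(unknown, code)
      next
    }
    kind <- COFACTOR_KINDS[[code]]
    if (kind == "FMN") {
      edge <- res[res$name %in% FMN_RING_ATOMS, , drop = FALSE]
      if (nrow(edge) < 10L)
        stop(sprintf("FMN residue %s/%d has only %d isoalloxazine ring atoms",
                     res$chain[1L], res$resno[1L], nrow(edge)))
    } else {
      fe <- res[toupper(res$element) == "FE", , drop = FALSE]
      if (nrow(fe) != FE_COUNT[[kind]])
        stop(sprintf("%s residue %s/%d has %d Fe atoms, expected %d",
                     code, res$chain[1L], res$resno[1L], nrow(fe),
                     FE_COUNT[[kind]]))
      edge <- fe
      if (edge_policy == "fe_and_s")
        edge <- res[toupper(res$element) %in% c("FE", "S"), , drop = FALSE]
    }
    out[[length(out) + 1L]] <- structure(
      list(kind = kind, resname = code, atoms = res, edge_atoms = edge,
           chain = res$chain[1L], resno = res$resno[1L],
           model = res$model[1L]),
      class = "redox_cofactor")
  }
  if (length(unknown))
    warning("ignoring unrecognised HET residue(s): ",
            paste(unique(unknown), collapse = ", "))
  out
}

#' @export
print.redox_cofactor <- function(x, ...) {
  cat(sprintf("<redox_cofactor> %s (%s) chain %s residue %d: %d atoms, %d edge atoms\n",
              x$kind, x$resname, x$chain, x$resno, nrow(x$atoms),
              nrow(x$edge_atoms)))
  invisible(x)
}

#' Split a parsed structure into a docked receptor-ligand complex
#'
#' Assigns chains and cofactors to the Fe-protein (receptor) side or the
#' electron-carrier (ligand) side of a docked two-body complex.  The Fe
#' protein is a homodimer; its chains are labelled `a` and `b` in ascending
#' chain-id order, a deterministic but arbitrary convention used when
#' reporting which protomer a salt bridge touches.
#'
#' @param atoms atom table from [parse_structure()].
#' @param receptor_chains character vector of receptor chain ids.
#' @param model_index which docking model this structure represents (1..3 by
#'   convention); also selects the MODEL block when the file has several.
#' @param edge_policy passed to [find_cofactors()].
#' @return A `docked_complex` object: atoms, receptor/ligand chain sets, the
#'   a/b chain-label map, and cofactors partitioned by side.
#' @export
split_receptor_ligand <- function(atoms, receptor_chains, model_index = 1L,
                                  edge_policy = c("fe_only", "fe_and_s")) {
  edge_policy <- match.arg(edge_policy)
  atoms <- atoms[atoms$model == model_index, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop(sprintf("no atoms in model %d", model_index))
  chains <- unique(atoms$chain)
  missing <- setdiff(receptor_chains, chains)
  if (length(missing))
    stop("receptor chain(s) not in structure: ", paste(missing, collapse = ", "))
  ligand_chains <- setdiff(chains, receptor_chains)
  if (length(ligand_chains) == 0L) stop("no ligand chains left in structure")

  cofs <- find_cofactors(atoms, edge_policy = edge_policy)
  on_receptor <- vapply(cofs, function(co) co$chain %in% receptor_chains, TRUE)
  rec_cofs <- cofs[on_receptor]
  lig_cofs <- cofs[!on_receptor]

  rec_fe4s4 <- Filter(function(co) co$kind == "FE4S4", rec_cofs)
  if (length(rec_fe4s4) != 1L)
    stop(sprintf("receptor cluster missing: expected exactly one [4Fe-4S] cluster on the receptor side, found %d",
                 length(rec_fe4s4)))
  if (length(lig_cofs) == 0L)
    stop("ligand carries no recognised redox cofactor")

  rc <- sort(receptor_chains)
  labels <- stats::setNames(letters[seq_along(rc)], rc)
  structure(
    list(model_index = as.integer(model_index),
         atoms = atoms,
         receptor_chains = rc,
         ligand_chains = sort(ligand_chains),
         chain_labels = labels,
         receptor_cofactors = rec_cofs,
         receptor_cluster = rec_fe4s4[[1L]],
         ligand_cofactors = lig_cofs),
    class = "docked_complex")
}

#' @export
print.docked_complex <- function(x, ...) {
  cat(sprintf("<docked_complex> model %d: receptor chains %s (labels %s), ligand chains %s\n",
              x$model_index, paste(x$receptor_chains, collapse = ","),
              paste(sprintf("%s=%s", x$chain_labels, names(x$chain_labels)),
                    collapse = ","),
              paste(x$ligand_chains, collapse = ",")))
  cat(sprintf("  ligand cofactors: %s\n",
              paste(vapply(x$ligand_cofactors, function(co) co$kind, ""),
                    collapse = ", ")))
  invisible(x)
}
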