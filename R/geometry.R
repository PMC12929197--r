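#' Edge-to-edge distance between two redox cofactors
#'
#' The edge-to-edge distance R is the minimum Euclidean distance over all
#' pairs of designated edge atoms (Fe atoms for FeS clusters, isoalloxazine
#' ring atoms for FMN).  The achieving atom pair is recorded.  The measure is
#' symmetric in its arguments.
#'
#' @param cofactor_a,cofactor_b `redox_cofactor` objects with non-empty
#'   edge-atom sets.
#' @return A `distance_measurement`: list with `R` (angstroms), the achieving
#'   `atom_a` and `atom_b` rows, and the two cofactor kinds.
#' @examples
#' cpx <- make_toy_complex(complex_spec(target_R = 8.5, seed = 3))
#' mod <- split_receptor_ligand(parse_structure(cpx$pdb),
#'                              receptor_chains = c("A", "B"))
#' edge_to_edge_distance(mod$receptor_cluster, mod$ligand_cofactors[[1]])$R
#' @export
edge_to_edge_distance <- function(cofactor_a, cofactor_b) {
  ea <- cofactor_a$edge_atoms
  eb <- cofactor_b$edge_atoms
  if (is.null(ea) || nrow(ea) == 0L || is.null(eb) || nrow(eb) == 0L)
    stop("empty edge-atom set")
  pa <- as.matrix(ea[, c("x", "y", "z")])
  pb <- as.matrix(eb[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  hit <- arrayInd(which.min(d2), dim(d2))
  structure(
    list(R = sqrt(d2[hit[1L], hit[2L]]),
         atom_a = ea[hit[1L], , drop = FALSE],
         atom_b = eb[hit[2L], , drop = FALSE],
         kind_a = cofactor_a$kind, kind_b = cofactor_b$kind),
    class = "distance_measurement")
}

#' @export
print.distance_measurement <- function(x, ...) {
  cat(sprintf("<distance_measurement> R = %.3f A  (%s %s/%d %s -- %s %s/%d %s)\n",
              x$R, x$kind_a, x$atom_a$chain, x$atom_a$resno, x$atom_a$name,
              x$kind_b, x$atom_b$chain, x$atom_b$resno, x$atom_b$name))
  invisible(x)
}

#' Nearest ligand cofactor to the receptor [4Fe-4S] cluster
#'
#' Carriers with two clusters (2\[4Fe-4S\] ferredoxins) need a selection
#' rule: the cofactor minimising R to the receptor cluster is taken as the
#' electron-transfer conduit.  Ties are broken towards the lower parent
#' residue number.
#'
#' @param model a `docked_complex`.
#' @return list with `cofactor` (the chosen `redox_cofactor`) and
#'   `measurement` (its `distance_measurement`, with `model_index` and
#'   `ligand_cofactor_kind` filled in).
#' @export
nearest_ligand_cofactor <- function(model) {
  stopifnot(inherits(model, "docked_complex"))
  meas <- lapply(model$ligand_cofactors, edge_to_edge_distance,
                 cofactor_a = model$receptor_cluster)
  R <- vapply(meas, function(m) m$R, 0)
  resno <- vapply(model$ligand_cofactors, function(co) co$resno, 0L)
  best <- order(R, resno)[1L]
  m <- meas[[best]]
  m$ligand_cofactor_kind <- model$ligand_cofactors[[best]]$kind
  m$model_index <- model$model_index
  list(cofactor = model$ligand_cofactors[[best]], measurement = m)
}

# side-chain charged-group heavy atoms; His excluded (protonation ambiguous),
# backbone termini excluded
CHARGED_ATOMS <- list(
  positive = list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ"),
  negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")))

charged_atom_table <- function(atoms, polarity) {
  spec <- CHARGED_ATOMS[[polarity]]
  keep <- rep(FALSE, nrow(atoms))
  for (rn in names(spec))
    keep <- keep | (atoms$resname == rn & atoms$name %in% spec[[rn]])
  atoms[keep, , drop = FALSE]
}

#' Enumerate interface salt bridges in a docked complex
#'
#' A salt bridge is called between a carrier (ligand) residue and an Fe-protein
#' (receptor) residue when the minimum distance between their side-chain
#' charged-group heavy atoms (Arg NE/NH1/NH2, Lys NZ vs Asp OD1/OD2,
#' Glu OE1/OE2, in either polarity) is at or below `cutoff`.  One bridge is
#' reported per residue pair, with the closest atom pair recorded; bridges are
#' sorted by distance.  The 4.0-angstrom default is the conventional
#' crystallographic criterion.
#'
#' @param model a `docked_complex`.
#' @param cutoff maximum charged-group atom distance in angstroms.
#' @return A data frame (class `salt_bridge_census`) with one row per bridge:
#'   `carrier_chain`, `carrier_resno`, `carrier_resname`, `fe_chain`,
#'   `fe_chain_label`, `fe_resno`, `fe_resname`, `pair_distance`, `polarity`
#'   (`"carrier_pos"` when the carrier supplies Arg/Lys, `"carrier_neg"`
#'   otherwise).
#' @export
find_salt_bridges <- function(model, cutoff = 4.0) {
  stopifnot(inherits(model, "docked_complex"), cutoff > 0)
  lig <- model$atoms[model$atoms$chain %in% model$ligand_chains, , drop = FALSE]
  rec <- model$atoms[model$atoms$chain %in% model$receptor_chains, , drop = FALSE]

  one_polarity <- function(carrier_pol, receptor_pol, tag) {
    ca <- charged_atom_table(lig, carrier_pol)
    ra <- charged_atom_table(rec, receptor_pol)
    if (nrow(ca) == 0L || nrow(ra) == 0L) return(NULL)
    pc <- as.matrix(ca[, c("x", "y", "z")])
    pr <- as.matrix(ra[, c("x", "y", "z")])
    d2 <- outer(rowSums(pc^2), rowSums(pr^2), "+") - 2 * pc %*% t(pr)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    df <- data.frame(
      carrier_chain = ca$chain[hit[, 1L]],
      carrier_resno = ca$resno[hit[, 1L]],
      carrier_resname = ca$resname[hit[, 1L]],
      fe_chain = ra$chain[hit[, 2L]],
      fe_resno = ra$resno[hit[, 2L]],
      fe_resname = ra$resname[hit[, 2L]],
      pair_distance = sqrt(d2[hit]),
      polarity = tag, stringsAsFactors = FALSE)
    # one bridge per residue pair: keep closest atom pair
    key <- paste(df$carrier_chain, df$carrier_resno, df$fe_chain, df$fe_resno)
    ord <- order(df$pair_distance)
    df <- df[ord, , drop = FALSE]
    df[!duplicated(key[ord]), , drop = FALSE]
  }

  out <- rbind(one_polarity("positive", "negative", "carrier_pos"),
               one_polarity("negative", "positive", "carrier_neg"))
  if (is.null(out))
    out <- data.frame(carrier_chain = character(0), carrier_resno = integer(0),
                      carrier_resname = character(0), fe_chain = character(0),
                      fe_resno = integer(0), fe_resname = character(0),
                      pair_distance = numeric(0), polarity = character(0),
                      stringsAsFactors = FALSE)
  out$fe_chain_label <- unname(model$chain_labels[out$fe_chain])
  out <- out[order(out$pair_distance), c(
    "carrier_chain", "carrier_resno", "carrier_resname", "fe_chain",
    "fe_chain_label", "fe_resno", "fe_resname", "pair_distance", "polarity")]
  rownames(out) <- NULL
  class(out) <- c("salt_bridge_census", "data.frame")
  out
}

#' Default Fe-protein hotspot residues
#'
#' Conserved charged residues on the *R. palustris* Fe protein implicated in
#' carrier binding: R101, R140, E112, E69.
#' @export
fe_protein_hotspots <- function() {
  data.frame(id = c("R101", "R140", "E112", "E69"),
             resno = c(101L, 140L, 112L, 69L),
             resname = c("ARG", "ARG", "GLU", "GLU"),
             stringsAsFactors = FALSE)
}

#' Group salt bridges by Fe-protein hotspot residue
#'
#' Maps each bridge of a census onto the conserved Fe-protein hotspot residues
#' it touches, keyed by hotspot id and homodimer chain label (a/b).  Bridges
#' to non-hotspot receptor residues stay in the census but are excluded from
#' the report.  Hotspot residues absent from the receptor numbering are
#' flagged with a warning and marked not-present.
#'
#' @param bridges a `salt_bridge_census` from [find_salt_bridges()].
#' @param model the `docked_complex` the census came from.
#' @param hotspots data frame with columns `id`, `resno`, `resname`
#'   (default [fe_protein_hotspots()]).
#' @return A `hotspot_report`: list with `contacts` (named list, one entry per
#'   hotspot x chain label, each a subset of the census) and `not_present`
#'   (hotspot ids missing from the receptor).
#' @export
hotspot_contacts <- function(bridges, model, hotspots = fe_protein_hotspots()) {
  stopifnot(inherits(model, "docked_complex"))
  rec <- model$atoms[model$atoms$chain %in% model$receptor_chains, , drop = FALSE]
  present <- vapply(seq_len(nrow(hotspots)), function(i)
    any(rec$resno == hotspots$resno[i] & rec$resname == hotspots$resname[i]),
    TRUE)
  if (any(!present))
    warning("hotspot residue(s) not present in receptor: ",
            paste(hotspots$id[!present], collapse = ", "))
  contacts <- list()
  for (i in seq_len(nrow(hotspots))) {
    for (lab in unname(model$chain_labels)) {
      key <- paste(hotspots$id[i], lab, sep = ".")
      contacts[[key]] <- if (!present[i]) NULL else
        bridges[bridges$fe_resno == hotspots$resno[i] &
                bridges$fe_resname == hotspots$resname[i] &
                bridges$fe_chain_label == lab, , drop = FALSE]
    }
  }
  structure(list(contacts = contacts,
                 not_present = hotspots$id[!present]),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat("<hotspot_report>\n")
  for (key in names(x$contacts)) {
    b <- x$contacts[[key]]
    cat(sprintf("  %-8s %s\n", key,
                if (is.null(b)) "not present"
                else sprintf("%d bridge(s)", nrow(b))))
  }
  invisible(x)
}
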