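# Synthetic two-body pseudo-complexes: minimal poly-alanine scaffolds with
# idealized cofactors and grafted charged residues.  Only the inter-cofactor
# minimum distance, the planted bridge geometry and PDB conformance are
# contractual; folds and stereochemistry are not.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

atom_row <- function(record, name, resname, chain, resno, xyz, element) {
  data.frame(record = record, serial = 0L, name = name, resname = resname,
             chain = chain, resno = as.integer(resno), icode = " ",
             x = xyz[1], y = xyz[2], z = xyz[3], element = element,
             model = 1L, stringsAsFactors = FALSE)
}

# idealized cubane [4Fe-4S]: Fe and S on alternating cube vertices,
# Fe-Fe edge 2.7 A
sf4_template <- function() {
  a <- 2.7 / sqrt(2)
  fe <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)) * a
  s  <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)) * a
  xyz <- rbind(fe, s)
  data.frame(name = c(paste0("FE", 1:4), paste0("S", 1:4)),
             element = c(rep("FE", 4), rep("S", 4)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             resname = "SF4", stringsAsFactors = FALSE)
}

# planar [2Fe-2S] rhombus, Fe-Fe 2.7 A
fes_template <- function() {
  data.frame(name = c("FE1", "FE2", "S1", "S2"),
             element = c("FE", "FE", "S", "S"),
             x = c(-1.35, 1.35, 0, 0), y = c(0, 0, 1.55, -1.55),
             z = c(0, 0, 0, 0), resname = "FES", stringsAsFactors = FALSE)
}

# partial cubane [3Fe-4S]
f3s_template <- function() {
  t <- sf4_template()
  t <- t[t$name != "FE4", , drop = FALSE]
  t$resname <- "F3S"
  t
}

# planar isoalloxazine: three fused hexagons (bond 1.4 A) give exactly the 14
# ring atoms; carbonyl O, ribityl chain and phosphate hang off as non-edge
# atoms
fmn_template <- function() {
  hexagon <- function(cx) {
    ang <- pi / 6 + (0:5) * pi / 3
    cbind(cx + 1.4 * cos(ang), 1.4 * sin(ang))
  }
  centers <- c(0, 1.4 * sqrt(3), 2 * 1.4 * sqrt(3))
  pts <- do.call(rbind, lapply(centers, hexagon))
  keep <- !duplicated(round(pts, 3))
  ring <- pts[keep, , drop = FALSE]
  stopifnot(nrow(ring) == 14L)
  ring <- ring[order(ring[, 1], ring[, 2]), , drop = FALSE]
  ring_names <- c("N1", "C2", "N3", "C4", "C4A", "N5", "C5A",
                  "C6", "C7", "C8", "C9", "C9A", "N10", "C10")
  ring_elem <- substr(ring_names, 1, 1)
  tail_names <- c("O2", "O4", "C1'", "C2'", "C3'", "C4'", "C5'", "O5'",
                  "P", "O1P", "O2P", "O3P")
  tail_elem <- c("O", "O", rep("C", 5), "O", "P", "O", "O", "O")
  n_tail <- length(tail_names)
  tail_xyz <- cbind(seq(0.8, by = 1.3, length.out = n_tail),
                    rep(3.0, n_tail), rep(0.5, n_tail))
  data.frame(name = c(ring_names, tail_names),
             element = c(ring_elem, tail_elem),
             x = c(ring[, 1], tail_xyz[, 1]),
             y = c(ring[, 2], tail_xyz[, 2]),
             z = c(rep(0, 14), tail_xyz[, 3]),
             resname = "FMN", stringsAsFactors = FALSE)
}

cofactor_template <- function(kind) {
  switch(kind,
         FE4S4 = sf4_template(), FE2S2 = fes_template(),
         FE3S4 = f3s_template(), FMN = fmn_template(),
         stop("unknown cofactor kind: ", kind))
}

# edge atoms of a template under the default fe_only policy
template_edge_idx <- function(tpl) {
  if (tpl$resname[1] == "FMN") which(tpl$name %in% FMN_RING_ATOMS)
  else which(tpl$element == "FE")
}

place_cofactor <- function(tpl, rot, shift) {
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, colMeans(xyz))          # centre on centroid
  xyz <- sweep(xyz, 2, shift, "+")
  tpl$x <- xyz[, 1]; tpl$y <- xyz[, 2]; tpl$z <- xyz[, 3]
  tpl
}

cofactor_atoms <- function(tpl, chain, resno) {
  do.call(rbind, lapply(seq_len(nrow(tpl)), function(i)
    atom_row("HETATM", tpl$name[i], tpl$resname[1], chain, resno,
             round(c(tpl$x[i], tpl$y[i], tpl$z[i]), 3), tpl$element[i])))
}

ala_chain <- function(chain, n_res, origin) {
  # schematic poly-alanine trace along y, 3.8 A spacing
  offs <- rbind(N = c(-0.9, -1.2, 0.3), CA = c(0, 0, 0), C = c(1.2, 0.6, -0.2),
                O = c(1.4, 1.8, -0.4), CB = c(-0.6, 0.6, 1.3))
  do.call(rbind, lapply(seq_len(n_res), function(k) {
    ctr <- origin + c(0, 3.8 * (k - 1), 0)
    do.call(rbind, lapply(rownames(offs), function(nm)
      atom_row("ATOM", nm, "ALA", chain, k,
               round(ctr + offs[nm, ], 3),
               substr(nm, 1, 1))))
  }))
}

# side-chain layouts: anchor = charged atom placed exactly at `anchor`, the
# rest trails along `dir` (+1 or -1 along x), away from the interface
charged_residue <- function(resname, chain, resno, anchor, dir) {
  off <- switch(resname,
    GLU = rbind(OE1 = c(0, 0, 0), OE2 = c(0.8, 1.0, 0), CD = c(1.1, -0.6, 0),
                CG = c(2.4, -0.3, 0.2), CB = c(3.6, 0.2, 0),
                CA = c(4.9, -0.1, 0.1), N = c(5.6, -1.3, 0),
                C = c(5.9, 1.1, 0), O = c(7.0, 1.4, 0.2)),
    ASP = rbind(OD1 = c(0, 0, 0), OD2 = c(0.8, 1.0, 0), CG = c(1.1, -0.6, 0),
                CB = c(2.4, -0.2, 0.1), CA = c(3.7, 0.1, 0),
                N = c(4.4, -1.2, 0), C = c(4.7, 1.3, 0), O = c(5.8, 1.5, 0.2)),
    ARG = rbind(NH1 = c(0, 0, 0), NH2 = c(0.7, 1.1, 0), CZ = c(0.9, -0.3, 0),
                NE = c(2.1, -0.8, 0), CD = c(3.3, -0.2, 0.1),
                CG = c(4.5, -0.6, 0), CB = c(5.7, -0.1, 0.1),
                CA = c(6.9, -0.5, 0), N = c(7.5, -1.7, 0),
                C = c(7.8, 0.8, 0), O = c(8.9, 1.0, 0.2)),
    LYS = rbind(NZ = c(0, 0, 0), CE = c(1.2, 0.5, 0), CD = c(2.4, 0, 0.1),
                CG = c(3.6, 0.5, 0), CB = c(4.8, 0, 0.1), CA = c(6.0, 0.4, 0),
                N = c(6.6, 1.6, 0), C = c(7.1, -0.8, 0), O = c(8.2, -1.1, 0.2)),
    stop("unsupported residue ", resname))
  off[, 1] <- dir * off[, 1]
  elem <- substr(rownames(off), 1, 1)
  do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    atom_row("ATOM", rownames(off)[i], resname, chain, resno,
             round(anchor + off[i, ], 3), elem[i])))
}

#' Specification of a synthetic docked pseudo-complex
#'
#' Describes a two-body complex the generator can build exactly: the minimum
#' edge-to-edge inter-cofactor distance, the ligand cofactor kind, optional
#' additional (farther) ligand cofactors, and a planted number of interface
#' salt bridges at a controlled atom-pair distance, plus charged decoy pairs
#' placed safely beyond the detection cutoff.
#'
#' @param target_R requested minimum edge-to-edge distance in angstroms
#'   (>= 2; honoured to within 0.001 angstroms after coordinate rounding).
#' @param ligand_cofactor_kind `"FE4S4"`, `"FE2S2"` or `"FMN"`.
#' @param n_extra_ligand_cofactors additional ligand cofactors placed strictly
#'   farther than `target_R`.
#' @param n_bridges number of planted Arg/Lys - Glu/Asp cross-interface salt
#'   bridges (alternating polarity; receptor residues use the conserved
#'   hotspot numbering 112, 101, 69, 140 first).
#' @param bridge_distance charged-group atom-pair distance of each planted
#'   bridge (default 3.5; must lie in (2, `cutoff`)).
#' @param decoy_charged_pairs charged cross-interface pairs planted at
#'   `cutoff + 1.5` angstroms, i.e. beyond detection.
#' @param cutoff the salt-bridge detection cutoff the fixture is built
#'   against (default 4.0).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return A `complex_spec` object.
#' @export
complex_spec <- function(target_R, ligand_cofactor_kind = "FE4S4",
                         n_extra_ligand_cofactors = 0L, n_bridges = 0L,
                         bridge_distance = 3.5, decoy_charged_pairs = 0L,
                         cutoff = 4.0, seed = 1L) {
  stopifnot(is.finite(target_R), target_R >= 2,
            ligand_cofactor_kind %in% c("FE4S4", "FE2S2", "FE3S4", "FMN"),
            n_extra_ligand_cofactors >= 0, n_bridges >= 0,
            decoy_charged_pairs >= 0, cutoff > 0, is.finite(seed))
  if (bridge_distance >= cutoff)
    stop("bridge_distance must be below the detection cutoff")
  if (bridge_distance <= 2)
    stop("bridge_distance below 2 A is sterically unsatisfiable")
  structure(list(target_R = target_R,
                 ligand_cofactor_kind = ligand_cofactor_kind,
                 n_extra_ligand_cofactors = as.integer(n_extra_ligand_cofactors),
                 n_bridges = as.integer(n_bridges),
                 bridge_distance = bridge_distance,
                 decoy_charged_pairs = as.integer(decoy_charged_pairs),
                 cutoff = cutoff, seed = as.integer(seed)),
            class = "complex_spec")
}

#' Generate a synthetic docked pseudo-complex as PDB text
#'
#' Builds a deterministic two-body complex honouring a [complex_spec()]: a
#' receptor homodimer surrogate (chains A and B, poly-alanine) carrying one
#' \[4Fe-4S\] cluster, and a ligand chain C carrying the requested
#' cofactor(s), with the minimum edge-to-edge distance equal to the requested
#' value to within 0.001 angstroms and exactly the planted number of salt
#' bridges at the stated cutoff.  Cofactors use idealized internal geometries
#' under seeded random orientations; the nearest edge-atom pair is placed
#' axis-aligned so the requested distance survives coordinate rounding.  The
#' generated structure is re-measured through the package's own pipeline
#' before being returned; a failed self-check is an error.
#'
#' @param spec a [complex_spec()].
#' @return A list with `pdb` (PDB text), `atoms` (the atom table) and
#'   `manifest` (ground truth: spec echo, measured distance, planted bridge
#'   table).
#' @examples
#' cpx <- make_toy_complex(complex_spec(target_R = 8.5, n_bridges = 3, seed = 7))
#' mod <- split_receptor_ligand(parse_structure(cpx$pdb), c("A", "B"))
#' nearest_ligand_cofactor(mod)$measurement$R
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  with_seed(spec$seed, {
    R <- round(spec$target_R, 3)

    # receptor [4Fe-4S] cluster, random orientation, centred at origin
    rec_tpl <- NULL
    for (try in 1:20) {
      cand <- place_cofactor(sf4_template(), random_rotation(), c(0, 0, 0))
      cand$x <- round(cand$x, 3); cand$y <- round(cand$y, 3)
      cand$z <- round(cand$z, 3)
      ex <- cand$x[template_edge_idx(cand)]
      if (max(ex) - sort(ex, decreasing = TRUE)[2] > 0.05) {
        rec_tpl <- cand; break
      }
    }
    if (is.null(rec_tpl)) stop("could not orient receptor cluster")
    eidx <- template_edge_idx(rec_tpl)
    p_i <- eidx[which.max(rec_tpl$x[eidx])]
    p <- c(rec_tpl$x[p_i], rec_tpl$y[p_i], rec_tpl$z[p_i])

    # ligand cofactor: its min-x edge atom lands exactly at p + (R, 0, 0);
    # require a unique minimum among edge atoms with clear margin so the
    # anchor pair stays the global minimum after coordinate rounding
    lig_tpl <- NULL
    for (try in 1:20) {
      cand <- place_cofactor(cofactor_template(spec$ligand_cofactor_kind),
                             random_rotation(), c(0, 0, 0))
      lx <- sort(cand$x[template_edge_idx(cand)])
      if (lx[2] - lx[1] > 0.05) { lig_tpl <- cand; break }
    }
    if (is.null(lig_tpl)) stop("could not orient ligand cofactor")
    leidx <- template_edge_idx(lig_tpl)
    q_i <- leidx[which.min(lig_tpl$x[leidx])]
    q_target <- p + c(R, 0, 0)
    shift <- q_target - c(lig_tpl$x[q_i], lig_tpl$y[q_i], lig_tpl$z[q_i])
    lig_tpl$x <- round(lig_tpl$x + shift[1], 3)
    lig_tpl$y <- round(lig_tpl$y + shift[2], 3)
    lig_tpl$z <- round(lig_tpl$z + shift[3], 3)
    # pin the anchor pair exactly
    lig_tpl$x[q_i] <- round(q_target[1], 3)
    lig_tpl$y[q_i] <- round(q_target[2], 3)
    lig_tpl$z[q_i] <- round(q_target[3], 3)

    atoms <- rbind(
      ala_chain("A", 8L, c(-12, -13, 0)),
      cofactor_atoms(rec_tpl, "A", 300L),
      ala_chain("B", 8L, c(-12, -13, 7)),
      ala_chain("C", 6L, c(q_target[1] + 10, -10, 0)),
      cofactor_atoms(lig_tpl, "C", 200L))

    # extra ligand cofactors, strictly farther out along +x
    extra_resno <- integer(0)
    for (k in seq_len(spec$n_extra_ligand_cofactors)) {
      far <- place_cofactor(cofactor_template(spec$ligand_cofactor_kind),
                            random_rotation(),
                            c(q_target[1] + 6 + 7 * k, 3 * k, 0))
      far$x <- round(far$x, 3); far$y <- round(far$y, 3)
      far$z <- round(far$z, 3)
      atoms <- rbind(atoms, cofactor_atoms(far, "C", 200L + k))
      extra_resno <- c(extra_resno, 200L + k)
    }

    # planted salt bridges along y, 12 A apart, alternating polarity;
    # receptor residues reuse the conserved hotspot numbering first
    xm <- p[1] + R / 2
    d <- spec$bridge_distance
    neg_nums <- c(112L, 69L, 152L, 154L, 156L, 158L, 160L, 162L)
    pos_nums <- c(101L, 140L, 151L, 153L, 155L, 157L, 159L, 161L)
    n_neg <- 0L; n_pos <- 0L
    bridge_truth <- NULL
    for (i in seq_len(spec$n_bridges)) {
      y <- 16 + 12 * (i - 1)
      rec_chain <- if (i %% 2L == 1L) "A" else "B"
      if (i %% 2L == 1L) {          # receptor negative, carrier positive
        n_neg <- n_neg + 1L
        if (n_neg > length(neg_nums)) stop("too many bridges requested")
        rn <- neg_nums[n_neg]
        atoms <- rbind(atoms,
          charged_residue("GLU", rec_chain, rn, c(xm - d / 2, y, 0), -1),
          charged_residue("LYS", "C", 50L + i, c(xm + d / 2, y, 0), +1))
        pol <- "carrier_pos"; rname <- "GLU"; cname <- "LYS"
      } else {                      # receptor positive, carrier negative
        n_pos <- n_pos + 1L
        if (n_pos > length(pos_nums)) stop("too many bridges requested")
        rn <- pos_nums[n_pos]
        atoms <- rbind(atoms,
          charged_residue("ARG", rec_chain, rn, c(xm - d / 2, y, 0), -1),
          charged_residue("GLU", "C", 50L + i, c(xm + d / 2, y, 0), +1))
        pol <- "carrier_neg"; rname <- "ARG"; cname <- "GLU"
      }
      bridge_truth <- rbind(bridge_truth, data.frame(
        carrier_resno = 50L + i, carrier_resname = cname,
        fe_chain = rec_chain, fe_resno = rn, fe_resname = rname,
        pair_distance = d, polarity = pol, stringsAsFactors = FALSE))
    }

    # decoy charged pairs beyond the cutoff, on the -y side
    d_decoy <- spec$cutoff + 1.5
    for (i in seq_len(spec$decoy_charged_pairs)) {
      y <- -16 - 12 * (i - 1)
      atoms <- rbind(atoms,
        charged_residue("ASP", "A", 400L + i, c(xm - d_decoy / 2, y, 0), -1),
        charged_residue("ARG", "C", 80L + i, c(xm + d_decoy / 2, y, 0), +1))
    }

    # group records by chain (receptor first), as a docking server would emit
    atoms <- atoms[order(match(atoms$chain, c("A", "B", "C"))), , drop = FALSE]
    atoms$serial <- seq_len(nrow(atoms))
    rownames(atoms) <- NULL
    pdb <- write_structure(atoms)

    # self-check: re-measure the fixture through the pipeline
    model <- split_receptor_ligand(parse_structure(pdb), c("A", "B"))
    near <- nearest_ligand_cofactor(model)
    if (abs(near$measurement$R - spec$target_R) > 1e-3)
      stop(sprintf("generator self-check failed: measured %.4f vs target %.4f",
                   near$measurement$R, spec$target_R))
    if (near$cofactor$resno != 200L)
      stop("generator self-check failed: an extra cofactor became nearest")
    bridges <- find_salt_bridges(model, cutoff = spec$cutoff)
    if (nrow(bridges) != spec$n_bridges)
      stop(sprintf("generator self-check failed: %d bridges found, %d planted",
                   nrow(bridges), spec$n_bridges))

    list(pdb = pdb, atoms = atoms,
         manifest = list(spec = unclass(spec),
                         measured_R = near$measurement$R,
                         n_bridges = spec$n_bridges,
                         bridges = bridge_truth,
                         extra_cofactor_resno = extra_resno,
                         receptor_chains = c("A", "B"),
                         ligand_chain = "C"))
  })
}

#' Specification of a synthetic carrier cohort
#'
#' Plants the group structure the screen is meant to detect: per-role carrier
#' counts, per-role distance and midpoint-potential distributions, and a
#' linear distance-activity model `activity = max(0, a + b * R + noise)` with
#' negative slope.  Role distance means default to 8.5 / 12 / 15.5 angstroms
#' (nif-linked / non-nif bacterial / plant), a synthetic separation mirroring
#' the qualitative ordering seen in docking screens, not measured values.
#'
#' @param n_per_role named counts for roles `nif`, `non_nif_bacterial`,
#'   `plant`.
#' @param distance_mean,distance_sd per-role normal parameters (angstroms);
#'   draws are truncated below at 4.
#' @param potential_mean,potential_sd per-role midpoint-potential normal
#'   parameters (mV).
#' @param activity_intercept,activity_slope,activity_noise_sd the linear
#'   activity model (slope in percent per angstrom, negative).
#' @param n_bridges_per_role planted salt bridges per role.
#' @param seed integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_role = c(nif = 6L, non_nif_bacterial = 6L,
                                       plant = 6L),
                        distance_mean = c(nif = 8.5, non_nif_bacterial = 12,
                                          plant = 15.5),
                        distance_sd = c(nif = 1.0, non_nif_bacterial = 1.5,
                                        plant = 1.5),
                        potential_mean = c(nif = -420,
                                           non_nif_bacterial = -430,
                                           plant = -380),
                        potential_sd = c(nif = 40, non_nif_bacterial = 60,
                                         plant = 40),
                        activity_intercept = 150, activity_slope = -8,
                        activity_noise_sd = 5,
                        n_bridges_per_role = c(nif = 3L,
                                               non_nif_bacterial = 1L,
                                               plant = 0L),
                        seed = 1L) {
  roles <- c("nif", "non_nif_bacterial", "plant")
  stopifnot(all(roles %in% names(n_per_role)),
            all(distance_sd >= 0), all(potential_sd >= 0),
            activity_noise_sd >= 0, activity_slope < 0)
  structure(list(n_per_role = n_per_role[roles],
                 distance_mean = distance_mean[roles],
                 distance_sd = distance_sd[roles],
                 potential_mean = potential_mean[roles],
                 potential_sd = potential_sd[roles],
                 activity_intercept = activity_intercept,
                 activity_slope = activity_slope,
                 activity_noise_sd = activity_noise_sd,
                 n_bridges_per_role = n_bridges_per_role[roles],
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic carrier cohort with planted structure
#'
#' For each synthetic carrier, draws three per-model docking distances from
#' its role's distribution (emulating three independent docking runs), a
#' midpoint potential, and an activity from the planted linear model
#' evaluated at the carrier's mean distance.  With `emit_complexes = TRUE`
#' each per-model distance is realised as a full PDB pseudo-complex via
#' [make_toy_complex()]; otherwise only the tables and manifest are built.
#' Plant carriers get \[2Fe-2S\] cofactors, bacterial carriers \[4Fe-4S\].
#'
#' @param spec a [cohort_spec()].
#' @param emit_complexes build PDB fixtures for every model (default TRUE).
#' @return A list with `carriers` (the pipeline's TSV dialect: carrier_id,
#'   organism, role_class, potential_mv_1, potential_mv_2, activity),
#'   `complexes` (named list: carrier id -> list of 3 [make_toy_complex()]
#'   outputs, or NULL), and `manifest` (every planted value).
#' @export
make_cohort <- function(spec, emit_complexes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    roles <- names(spec$n_per_role)
    short <- c(nif = "nif", non_nif_bacterial = "bac", plant = "plt")
    rows <- list(); planted <- list(); complexes <- list()
    for (role in roles) {
      for (j in seq_len(spec$n_per_role[[role]])) {
        id <- sprintf("syn_%s_%02d", short[[role]], j)
        dists <- pmax(4, stats::rnorm(3, spec$distance_mean[[role]],
                                      spec$distance_sd[[role]]))
        dists <- round(dists, 3)
        pot <- round(stats::rnorm(1, spec$potential_mean[[role]],
                                  spec$potential_sd[[role]]))
        mean_R <- mean(dists)
        act <- max(0, spec$activity_intercept +
                      spec$activity_slope * mean_R +
                      stats::rnorm(1, 0, spec$activity_noise_sd))
        seeds <- sample.int(1000000L, 3)
        rows[[id]] <- data.frame(
          carrier_id = id, organism = "synthetic", role_class = role,
          potential_mv_1 = pot, potential_mv_2 = NA_real_,
          activity = act, stringsAsFactors = FALSE)
        planted[[id]] <- list(role_class = role, distances = dists,
                              mean_R = mean_R, potential_mV = pot,
                              activity = act, model_seeds = seeds)
        if (emit_complexes) {
          kind <- if (role == "plant") "FE2S2" else "FE4S4"
          complexes[[id]] <- lapply(1:3, function(m)
            make_toy_complex(complex_spec(
              target_R = dists[m], ligand_cofactor_kind = kind,
              n_bridges = spec$n_bridges_per_role[[role]],
              seed = seeds[m])))
        }
      }
    }
    list(carriers = do.call(rbind, c(rows, make.row.names = FALSE)),
         complexes = if (emit_complexes) complexes else NULL,
         manifest = list(spec = unclass(spec), carriers = planted))
  })
}

#' Run the full screen over a synthetic cohort
#'
#' Convenience wrapper: parses every generated complex, measures distances,
#' evaluates each carrier, counts salt bridges on its first model, and fits
#' the distance-activity regression.
#'
#' @param cohort output of [make_cohort()] with complexes emitted.
#' @param params a [tunneling_params()] object.
#' @param acceptor_potential_mV Fe-protein midpoint potential (default -415).
#' @param cutoff salt-bridge cutoff in angstroms.
#' @return list with `calls` (per-carrier `compatibility_call`s), `summary`
#'   (a `cohort_summary`), `fit` (`distance_activity_fit`), and `bridges`
#'   (named list of censuses).
#' @export
measure_cohort <- function(cohort, params = tunneling_params(),
                           acceptor_potential_mV = -415, cutoff = 4.0) {
  stopifnot(!is.null(cohort$complexes))
  carriers <- cohort$carriers
  calls <- list(); bridges <- list()
  for (i in seq_len(nrow(carriers))) {
    id <- carriers$carrier_id[i]
    models <- lapply(seq_along(cohort$complexes[[id]]), function(m) {
      mod <- split_receptor_ligand(
        parse_structure(cohort$complexes[[id]][[m]]$pdb), c("A", "B"))
      mod$model_index <- m
      mod
    })
    calls[[id]] <- evaluate_carrier(models, carriers[i, ], params,
                                    acceptor_potential_mV)
    bridges[[id]] <- find_salt_bridges(models[[1L]], cutoff = cutoff)
  }
  mean_R <- vapply(calls, function(x) x$mean_R, 0)
  fit <- fit_distance_activity(mean_R, carriers$activity)
  list(calls = calls, summary = classify_cohort(calls), fit = fit,
       bridges = bridges)
}
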