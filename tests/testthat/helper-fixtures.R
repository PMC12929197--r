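# in-code fixtures: hand-built atom tables and PDB text, plus independent
# oracles used across the suite

# one fixed-width ATOM/HETATM line
pdb_line <- function(record = "ATOM", serial = 1, name = "CA",
                     resname = "ALA", chain = "A", resno = 1,
                     x = 0, y = 0, z = 0, element = "C", altloc = " ") {
  pad <- if (nchar(element) >= 2 || nchar(name) >= 4)
    formatC(name, width = -4) else paste0(" ", formatC(name, width = -3))
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, pad, altloc, resname, chain, resno, x, y, z, element)
}

# minimal atom-table row matching parse_structure() output
fx_atom <- function(record, name, resname, chain, resno, x, y, z, element,
                    model = 1L) {
  data.frame(record = record, serial = 0L, name = name, resname = resname,
             chain = chain, resno = as.integer(resno), icode = " ",
             x = x, y = y, z = z, element = element, model = model,
             stringsAsFactors = FALSE)
}

# idealized SF4 as atom rows at a given centre
fx_sf4 <- function(chain, resno, centre = c(0, 0, 0)) {
  a <- 2.7 / sqrt(2)
  fe <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)) * a
  s <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)) * a
  xyz <- sweep(rbind(fe, s), 2, colMeans(rbind(fe, s)))
  xyz <- sweep(xyz, 2, centre, "+")
  do.call(rbind, lapply(1:8, function(i)
    fx_atom("HETATM", c(paste0("FE", 1:4), paste0("S", 1:4))[i], "SF4",
            chain, resno, xyz[i, 1], xyz[i, 2], xyz[i, 3],
            c(rep("FE", 4), rep("S", 4))[i])))
}

fx_fes <- function(chain, resno, centre = c(0, 0, 0)) {
  xyz <- rbind(c(-1.35, 0, 0), c(1.35, 0, 0), c(0, 1.55, 0), c(0, -1.55, 0))
  xyz <- sweep(xyz, 2, centre, "+")
  do.call(rbind, lapply(1:4, function(i)
    fx_atom("HETATM", c("FE1", "FE2", "S1", "S2")[i], "FES", chain, resno,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], c("FE", "FE", "S", "S")[i])))
}

# a minimal docked complex: receptor chains A,B (A carries SF4 at origin),
# ligand chain C (FES centred `lig_centre`); extra atom rows appended
fx_complex <- function(lig_centre = c(10, 0, 0), extra = NULL,
                       lig = fx_fes("C", 200, lig_centre)) {
  atoms <- rbind(
    fx_atom("ATOM", "CA", "ALA", "A", 1, -10, 0, 0, "C"),
    fx_sf4("A", 300),
    fx_atom("ATOM", "CA", "ALA", "B", 1, -10, 5, 0, "C"),
    fx_atom("ATOM", "CA", "ALA", "C", 1, 20, 0, 0, "C"),
    lig, extra)
  atoms$serial <- seq_len(nrow(atoms))
  split_receptor_ligand(atoms, c("A", "B"))
}

# a bare cofactor object from explicit edge-atom coordinates
fx_cofactor <- function(xyz, kind = "FE4S4", resno = 1L, chain = "X") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  atoms <- do.call(rbind, lapply(seq_len(nrow(xyz)), function(i)
    fx_atom("HETATM", paste0("FE", i), "SF4", chain, resno,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], "FE")))
  structure(list(kind = kind, resname = "SF4", atoms = atoms,
                 edge_atoms = atoms, chain = chain, resno = as.integer(resno),
                 model = 1L),
            class = "redox_cofactor")
}

# independent oracle: the tunneling ruler written out directly
oracle_log10k <- function(R, dg, lambda = 0.65, rho = 0.76) {
  base <- 13.0 - (1.2 - 0.8 * rho) * (R - 3.6)
  if (dg <= 0) base - 3.1 * (dg + lambda)^2 / lambda
  else base - 3.1 * (-dg + lambda)^2 / lambda - dg / 0.06
}

# brute-force minimum cross-pair distance
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# interpolated order statistic (type-7 quantile) written out directly
oracle_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}
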