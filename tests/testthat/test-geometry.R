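test_that("edge-to-edge distance is the minimum cross pair and is symmetric", {
  a <- fx_cofactor(c(0, 0, 0))
  b <- fx_cofactor(c(10, 0, 0))
  expect_equal(edge_to_edge_distance(a, b)$R, 10)

  a2 <- fx_cofactor(c(0, 0, 0, 2, 0, 0))
  b2 <- fx_cofactor(c(9, 0, 0, 20, 0, 0))
  m <- edge_to_edge_distance(a2, b2)
  expect_equal(m$R, 7)
  expect_equal(m$atom_a$x, 2)
  expect_equal(m$atom_b$x, 9)
  expect_identical(edge_to_edge_distance(b2, a2)$R, m$R)

  empty <- a; empty$edge_atoms <- empty$edge_atoms[0, ]
  expect_error(edge_to_edge_distance(empty, b), "empty edge-atom")
})

test_that("minimum property holds against brute force on random small sets", {
  set.seed(42)
  for (rep in 1:25) {
    na <- sample(1:10, 1); nb <- sample(1:10, 1)
    pa <- matrix(stats::runif(3 * na, -20, 20), ncol = 3)
    pb <- matrix(stats::runif(3 * nb, -20, 20), ncol = 3)
    a <- fx_cofactor(as.vector(t(pa)))
    b <- fx_cofactor(as.vector(t(pb)))
    m <- edge_to_edge_distance(a, b)
    expect_equal(m$R, oracle_min_dist(pa, pb), tolerance = 1e-12)
    # R is a lower bound on every cross pair
    for (i in seq_len(na)) for (j in seq_len(nb))
      expect_lte(m$R, sqrt(sum((pa[i, ] - pb[j, ])^2)) + 1e-12)
  }
})

test_that("nearest ligand cofactor selection and tie-breaking", {
  two <- rbind(fx_fes("C", 201, c(8, 0, 0)), fx_fes("C", 202, c(15, 0, 0)))
  mod <- fx_complex(lig = two)
  near <- nearest_ligand_cofactor(mod)
  expect_equal(near$cofactor$resno, 201L)
  expect_lt(near$measurement$R, 8)

  one <- fx_complex()
  expect_equal(nearest_ligand_cofactor(one)$cofactor$resno, 200L)

  # exact tie (both 10.0), lower residue number wins
  modt <- structure(list(
    model_index = 1L,
    receptor_cluster = fx_cofactor(c(0, 0, 0)),
    ligand_cofactors = list(fx_cofactor(c(10, 0, 0), resno = 210),
                            fx_cofactor(c(-10, 0, 0), resno = 205))),
    class = "docked_complex")
  expect_equal(nearest_ligand_cofactor(modt)$cofactor$resno, 205L)
  expect_equal(nearest_ligand_cofactor(modt)$measurement$R, 10)
})

test_that("salt bridges are called at the cutoff with correct polarity", {
  glu <- rbind(fx_atom("ATOM", "OE1", "GLU", "A", 112, 3, 8, 0, "O"),
               fx_atom("ATOM", "OE2", "GLU", "A", 112, 2.2, 9, 0, "O"))
  lys_close <- fx_atom("ATOM", "NZ", "LYS", "C", 51, 6.5, 8, 0, "N")
  mod <- fx_complex(extra = rbind(glu, lys_close))
  b <- find_salt_bridges(mod, cutoff = 4)
  expect_equal(nrow(b), 1L)
  expect_equal(b$pair_distance, 3.5)
  expect_equal(b$polarity, "carrier_pos")
  expect_equal(b$fe_resno, 112L)
  expect_equal(b$fe_chain_label, "a")

  lys_far <- fx_atom("ATOM", "NZ", "LYS", "C", 51, 7.5, 8, 0, "N")
  modf <- fx_complex(extra = rbind(glu, lys_far))
  expect_equal(nrow(find_salt_bridges(modf, cutoff = 4)), 0L)
  # boundary is inclusive; enlarging the cutoff never removes a bridge
  expect_equal(nrow(find_salt_bridges(modf, cutoff = 4.5)), 1L)
  expect_equal(nrow(find_salt_bridges(modf, cutoff = 6)), 1L)
})

test_that("one bridge per residue pair, closest atom pair recorded", {
  glu <- rbind(fx_atom("ATOM", "OE1", "GLU", "A", 69, 3, 8, 0, "O"),
               fx_atom("ATOM", "OE2", "GLU", "A", 69, 3.2, 8, 0, "O"))
  arg <- rbind(fx_atom("ATOM", "NH1", "ARG", "C", 51, 6.2, 8, 0, "N"),
               fx_atom("ATOM", "NH2", "ARG", "C", 51, 6.4, 8, 0, "N"))
  b <- find_salt_bridges(fx_complex(extra = rbind(glu, arg)), cutoff = 4)
  expect_equal(nrow(b), 1L)
  expect_equal(b$pair_distance, 3.0)
})

test_that("planted bridge counts are recovered from generated complexes", {
  for (n in c(0L, 1L, 3L, 5L)) {
    cpx <- make_toy_complex(complex_spec(target_R = 9, n_bridges = n,
                                         decoy_charged_pairs = 2, seed = n + 1))
    mod <- split_receptor_ligand(parse_structure(cpx$pdb), c("A", "B"))
    b <- find_salt_bridges(mod, cutoff = 4)
    expect_equal(nrow(b), n)
    if (n > 0) expect_equal(b$pair_distance, rep(3.5, n), tolerance = 1e-3)
  }
})

test_that("census is invariant under swapping homodimer chain labels", {
  cpx <- make_toy_complex(complex_spec(target_R = 8, n_bridges = 4, seed = 6))
  atoms <- parse_structure(cpx$pdb)
  swapped <- atoms
  swapped$chain[atoms$chain == "A"] <- "B"
  swapped$chain[atoms$chain == "B"] <- "A"
  b1 <- find_salt_bridges(split_receptor_ligand(atoms, c("A", "B")), 4)
  b2 <- find_salt_bridges(split_receptor_ligand(swapped, c("A", "B")), 4)
  cols <- c("carrier_resno", "fe_resno", "pair_distance", "polarity")
  expect_equal(b1[order(b1$fe_resno), cols],
               b2[order(b2$fe_resno), cols], ignore_attr = TRUE)
  # only the a/b annotation flips
  expect_equal(sort(b1$fe_chain_label), sort(chartr("ab", "ba", b2$fe_chain_label)))
})

test_that("hotspot contacts group bridges by conserved residue and protomer", {
  glu <- fx_atom("ATOM", "OE1", "GLU", "C", 51, 6.5, 8, 0, "O")
  arg101 <- fx_atom("ATOM", "NH1", "ARG", "A", 101, 3, 8, 0, "N")
  arg140 <- fx_atom("ATOM", "NH1", "ARG", "B", 140, -3, -8, 0, "N")
  e112 <- fx_atom("ATOM", "OE1", "GLU", "A", 112, -5, 12, 0, "O")
  e69 <- fx_atom("ATOM", "OE1", "GLU", "B", 69, -5, -12, 0, "O")
  mod <- fx_complex(extra = rbind(glu, arg101, arg140, e112, e69))
  b <- find_salt_bridges(mod, cutoff = 4)
  rep <- hotspot_contacts(b, mod)
  expect_equal(nrow(rep$contacts[["R101.a"]]), 1L)
  expect_equal(nrow(rep$contacts[["R101.b"]]), 0L)
  expect_equal(nrow(rep$contacts[["E112.a"]]), 0L)
  expect_length(rep$not_present, 0L)

  # no bridges at all: every key maps to an empty set
  rep0 <- hotspot_contacts(find_salt_bridges(mod, cutoff = 2.5), mod)
  expect_true(all(vapply(rep0$contacts, nrow, 0L) == 0L))
})

test_that("non-hotspot bridges stay in the census but leave the report empty", {
  glu55 <- fx_atom("ATOM", "OE1", "GLU", "A", 55, 3, 8, 0, "O")
  arg101 <- fx_atom("ATOM", "NH1", "ARG", "A", 101, -14, 8, 0, "N")
  e112 <- fx_atom("ATOM", "OE1", "GLU", "A", 112, -14, 12, 0, "O")
  e69 <- fx_atom("ATOM", "OE1", "GLU", "A", 69, -14, -12, 0, "O")
  arg140 <- fx_atom("ATOM", "NH1", "ARG", "A", 140, -14, -8, 0, "N")
  lys <- fx_atom("ATOM", "NZ", "LYS", "C", 51, 6.5, 8, 0, "N")
  mod <- fx_complex(extra = rbind(glu55, arg101, arg140, e112, e69, lys))
  b <- find_salt_bridges(mod, cutoff = 4)
  expect_equal(nrow(b), 1L)
  rep <- hotspot_contacts(b, mod)
  expect_true(all(vapply(rep$contacts, nrow, 0L) == 0L))

  # a hotspot residue absent from the receptor is flagged
  mod2 <- fx_complex(extra = rbind(glu55, lys))
  expect_warning(rep2 <- hotspot_contacts(find_salt_bridges(mod2, 4), mod2),
                 "not present")
  expect_setequal(rep2$not_present, c("R101", "R140", "E112", "E69"))
})
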