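test_that("generation is a pure function of the spec", {
  s <- complex_spec(target_R = 8.5, n_bridges = 3, seed = 7)
  a <- make_toy_complex(s)
  b <- make_toy_complex(s)
  expect_identical(a$pdb, b$pdb)
  # and does not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(make_toy_complex(s)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("requested distance and bridge counts are honoured exactly", {
  cpx <- make_toy_complex(complex_spec(target_R = 8.5, n_bridges = 3,
                                       seed = 7))
  mod <- split_receptor_ligand(parse_structure(cpx$pdb), c("A", "B"))
  expect_equal(nearest_ligand_cofactor(mod)$measurement$R, 8.5,
               tolerance = 1e-3)
  expect_equal(nrow(find_salt_bridges(mod, 4)), 3L)
  expect_equal(cpx$manifest$measured_R, 8.5, tolerance = 1e-3)
  expect_equal(nrow(cpx$manifest$bridges), 3L)
})

test_that("each requested ligand cofactor kind is detected after round trip", {
  for (kind in c("FE4S4", "FE2S2", "FMN")) {
    cpx <- make_toy_complex(complex_spec(target_R = 10, seed = 5,
                                         ligand_cofactor_kind = kind))
    mod <- split_receptor_ligand(parse_structure(cpx$pdb), c("A", "B"))
    expect_equal(mod$ligand_cofactors[[1]]$kind, kind)
    expect_equal(nearest_ligand_cofactor(mod)$measurement$R, 10,
                 tolerance = 1e-3)
  }
})

test_that("extra ligand cofactors never become the nearest cluster", {
  for (s in 1:6) {
    cpx <- make_toy_complex(complex_spec(target_R = 9, seed = s,
                                         n_extra_ligand_cofactors = 2))
    mod <- split_receptor_ligand(parse_structure(cpx$pdb), c("A", "B"))
    expect_length(mod$ligand_cofactors, 3L)
    near <- nearest_ligand_cofactor(mod)
    expect_equal(near$cofactor$resno, 200L)
    expect_equal(near$measurement$R, 9, tolerance = 1e-3)
  }
})

test_that("unsatisfiable specs are rejected before emission", {
  expect_error(complex_spec(target_R = 8, bridge_distance = 4.5),
               "cutoff")
  expect_error(complex_spec(target_R = 8, bridge_distance = 1.5),
               "unsatisfiable")
  expect_error(complex_spec(target_R = -3))
})

test_that("cohorts carry planted values in manifest and tables", {
  spec <- cohort_spec(n_per_role = c(nif = 2L, non_nif_bacterial = 2L,
                                     plant = 2L), seed = 9)
  co <- make_cohort(spec, emit_complexes = FALSE)
  expect_equal(nrow(co$carriers), 6L)
  expect_setequal(unique(co$carriers$role_class),
                  c("nif", "non_nif_bacterial", "plant"))
  expect_length(co$manifest$carriers, 6L)
  # activity follows the planted linear model at the planted mean distance
  for (id in names(co$manifest$carriers)) {
    m <- co$manifest$carriers[[id]]
    expect_equal(length(m$distances), 3L)
    expect_equal(m$mean_R, mean(m$distances))
    expect_gte(m$activity, 0)
  }
  co2 <- make_cohort(spec, emit_complexes = FALSE)
  expect_identical(co$carriers, co2$carriers)
})

test_that("the measurement pipeline recovers planted cohort structure", {
  spec <- cohort_spec(n_per_role = c(nif = 3L, non_nif_bacterial = 3L,
                                     plant = 3L), seed = 21)
  co <- make_cohort(spec)
  res <- measure_cohort(co)
  # measured mean distances equal planted ones
  for (id in names(res$calls))
    expect_equal(res$calls[[id]]$mean_R, co$manifest$carriers[[id]]$mean_R,
                 tolerance = 1e-3)
  # role medians sit near the planted 8.5 / 12 / 15.5 separation
  st <- res$summary$stats
  med <- stats::setNames(st$R_median, st$role_class)
  expect_lt(abs(med[["nif"]] - 8.5), 2)
  expect_lt(abs(med[["non_nif_bacterial"]] - 12), 2.5)
  expect_lt(abs(med[["plant"]] - 15.5), 2.5)
  expect_true(med[["nif"]] < med[["non_nif_bacterial"]])
  expect_true(med[["non_nif_bacterial"]] < med[["plant"]])
  # planted bridge counts per role
  expect_equal(nrow(res$bridges[["syn_nif_01"]]), 3L)
  expect_equal(nrow(res$bridges[["syn_plt_01"]]), 0L)
  # regression slope has the planted (negative) sign
  expect_lt(res$fit$slope, 0)
})
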