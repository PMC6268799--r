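test_that("three-point superposition recovers constructed rigid motions", {
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(1, 1, 1), c(-1, 2, 0.5))
  al <- alignment_spec("a", c(1, 2, 3))
  # identity
  out <- superpose_three_point(ref, ref, al)
  expect_equal(out, ref, tolerance = 1e-10)
  # 90-degree rotation about z plus translation, then recovery
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  moved <- sweep(ref %*% t(Rz), 2, -c(1, 2, 3))
  back <- superpose_three_point(moved, ref, al)
  expect_equal(back, ref, tolerance = 1e-10)
  # random proper rotations, all atoms recovered (not only the triple)
  set.seed(1)
  for (i in 1:10) {
    R <- random_rotation()
    t <- rnorm(3)
    moved <- sweep(ref %*% t(R), 2, -t)
    expect_equal(superpose_three_point(moved, ref, al), ref,
                 tolerance = 1e-8)
  }
})

test_that("collinear alignment atoms are rejected", {
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(5, 5, 5))
  al <- alignment_spec("a", c(1, 2, 3))
  expect_error(superpose_three_point(bad, bad, al), "collinear")
  expect_error(alignment_spec("a", c(1, 1, 2)), "distinct")
})

test_that("superposition never reflects", {
  set.seed(7)
  ref <- matrix(rnorm(15), 5)
  al <- alignment_spec("a", c(1, 2, 3))
  for (i in 1:20) {
    mob <- matrix(rnorm(15), 5)
    if (qsar4d:::.collinear(mob[1:3, ]) || qsar4d:::.collinear(ref[1:3, ])) next
    out <- superpose_three_point(mob, ref, al)
    # recover the applied linear map from displaced simplex; must be proper
    A <- t(out[2:4, ] - matrix(out[1, ], 3, 3, byrow = TRUE)) %*%
      solve(t(mob[2:4, ] - matrix(mob[1, ], 3, 3, byrow = TRUE)))
    expect_gt(det(A), 0)
  }
})

test_that("IPE typing follows the pharmacophore table", {
  pip <- toy_piperidinium()
  m <- assign_ipe(pip)
  expect_true(all(m[, "any"]))
  # protonated piperidine nitrogen: polar-positive donor, no free lone pair
  expect_true(m[1, "p+"])
  expect_true(m[1, "hbd"])
  expect_false(m[1, "hba"])
  expect_false(m[1, "ar"])
  # its hydrogens are polar-positive donors too
  expect_true(all(m[7:8, c("p+", "hbd")]))
  # saturated ring carbons are np, not aromatic
  expect_true(all(m[2:6, "np"]))
  expect_false(any(m[2:6, "ar"]))

  ph <- toy_phenol()
  m2 <- assign_ipe(ph)
  # phenolic oxygen: polar-negative, acceptor and donor
  expect_true(m2[7, "p-"])
  expect_true(m2[7, "hba"])
  expect_true(m2[7, "hbd"])
  # ring carbons: aromatic nonpolar
  expect_true(all(m2[1:6, "ar"]))
  expect_true(all(m2[1:6, "np"]))
  expect_false(any(m2[1:6, "p+"] | m2[1:6, "p-"]))
  # ring hydrogens inherit np from carbon; hydroxyl H is a donor
  expect_true(all(m2[9:13, "np"]))
  expect_true(m2[8, "hbd"])

  expect_error(assign_ipe(list(elements = c("C", "Xx"), bonds = NULL)),
               "Xx")
})

test_that("grid cell indexing uses half-open cells centered on the lattice", {
  g <- grid_spec(1.0)
  # default registration: cell (x,y,z) spans [x-0.5, x+0.5) per axis
  expect_equal(cell_index(rbind(c(0.2, 0.9, -0.1)), g),
               matrix(c(0L, 1L, 0L), 1))
  expect_equal(cell_index(rbind(c(1.0, -1.0, 2.5)), g),
               matrix(c(1L, -1L, 3L), 1))
  expect_equal(cell_index(rbind(c(-0.5, 0.5, 0)), g),
               matrix(c(0L, 1L, 0L), 1))  # half-open: boundary joins above
  g2 <- grid_spec(2.0, origin = c(-1, -1, -1))
  expect_equal(cell_index(rbind(c(0, 0, 0)), g2), matrix(c(0L, 0L, 0L), 1))
  expect_equal(cell_index(rbind(c(2.9, -1.1, 0)), g2),
               matrix(c(1L, -1L, 0L), 1))
})

test_that("inter-cell distances reproduce the printed lattice geometry", {
  expect_equal(round(cell_center_distance(c(1, 13, 1), c(-1, 8, 2), 1.0), 2),
               5.48)
  expect_equal(round(cell_center_distance(c(0, 1, -2), c(0, -2, -1), 1.0), 2),
               3.16)
  expect_equal(round(cell_center_distance(c(0, 10, -2), c(0, 12, -1), 1.0), 2),
               2.24)
  expect_equal(round(cell_center_distance(c(0, 2, 2), c(1, 3, 6), 1.0), 2),
               4.24)
  expect_equal(cell_center_distance(c(3, -1, 2), c(3, -1, 2), 1.0), 0)
  # scales linearly with cell size
  expect_equal(cell_center_distance(c(0, 1, -2), c(0, -2, -1), 2.0),
               2 * cell_center_distance(c(0, 1, -2), c(0, -2, -1), 1.0))
})

test_that("occupancy counts occupations and normalizes by CEP size", {
  # one np atom sitting in cell (0,0,0) for a single conformation
  ens <- one_conf_ensemble(rbind(c(0.2, -0.3, 0.1)), "C")
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  occ <- compute_gcods(list(ens), ref, alignment_spec("a", 1:3),
                       grid_spec(1.0), align = FALSE)
  expect_equal(unname(occ[1, "(0,0,0)|any"]), 1.0)
  expect_equal(unname(occ[1, "(0,0,0)|np"]), 1.0)

  # atom in a cell for 500 of 2000 conformations -> 0.25
  n <- 2000
  coords <- array(0, dim = c(1, 3, n))
  coords[1, 1, ] <- c(rep(0.2, 500), rep(1.2, 1500))
  ens2 <- conformer_ensemble("c", coords, rep(0, n), "C")
  occ2 <- compute_gcods(list(ens2), ref, alignment_spec("a", 1:3),
                        grid_spec(1.0), align = FALSE)
  expect_equal(unname(occ2[1, "(0,0,0)|any"]), 0.25)
  expect_equal(unname(occ2[1, "(1,0,0)|any"]), 0.75)

  # multiple aromatic atoms in one cell each count: occupancy is uncapped
  ph <- toy_phenol()
  ens6 <- one_conf_ensemble(ph$coords, ph$elements, bonds = ph$bonds)
  occ6 <- compute_gcods(list(ens6), ref, alignment_spec("a", 1:3),
                        grid_spec(10.0), align = FALSE)
  ar_cols <- grep("\\|ar$", colnames(occ6), value = TRUE)
  expect_equal(sum(occ6[1, ar_cols]), 6)   # all six ring atoms counted
  expect_true(max(occ6[1, ar_cols]) > 1)   # several per cell, uncapped
})

test_that("occupancy is invariant to a global rigid motion of the inputs", {
  set.seed(21)
  ref <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0),
               matrix(rnorm(9, sd = 2), 3))
  al <- alignment_spec("a", 1:3)
  g <- grid_spec(1.0)
  mk <- function(shift) {
    coords <- array(NA_real_, dim = c(6, 3, 5))
    for (k in 1:5) coords[, , k] <- ref + matrix(rnorm(18, 0, 0.2), 6)
    coords
  }
  base <- mk()
  ens <- conformer_ensemble("m", base, rep(0, 5), rep("C", 6))
  occ <- compute_gcods(list(ens), ref, al, g)
  R <- random_rotation()
  t <- c(3.2, -1.1, 0.7)
  moved <- base
  for (k in 1:5) moved[, , k] <- sweep(base[, , k] %*% t(R), 2, -t)
  ens_m <- conformer_ensemble("m", moved, rep(0, 5), rep("C", 6))
  occ_m <- compute_gcods(list(ens_m), ref, al, g)
  expect_equal(colnames(occ_m), colnames(occ))
  expect_equal(unname(occ_m), unname(occ), tolerance = 1e-10)
})

test_that("`any` occupancy dominates every class and sums to atoms per conformation", {
  ph <- toy_phenol()
  coords <- array(NA_real_, dim = c(13, 3, 8))
  set.seed(5)
  for (k in 1:8) coords[, , k] <- ph$coords + matrix(rnorm(39, 0, 0.3), 13)
  ens <- conformer_ensemble("p", coords, rep(0, 8), ph$elements,
                            bonds = ph$bonds)
  ref <- ph$coords
  occ <- compute_gcods(list(ens), ref, alignment_spec("a", c(1, 3, 5)),
                       grid_spec(1.0))
  keys <- parse_gcod_key(colnames(occ))
  for (ipe in setdiff(unique(keys$ipe), "any")) {
    sel <- keys$ipe == ipe
    any_keys <- sprintf("(%d,%d,%d)|any", keys$x[sel], keys$y[sel],
                        keys$z[sel])
    expect_true(all(occ[1, any_keys] >= occ[1, colnames(occ)[sel]]))
  }
  expect_equal(sum(occ[1, keys$ipe == "any"]), 13)
})

test_that("ensemble occupancy equals the average of per-conformer occupancies", {
  mol <- toy_chain4()
  coords <- array(NA_real_, dim = c(4, 3, 6))
  set.seed(9)
  for (k in 1:6) coords[, , k] <- mol$coords + matrix(rnorm(12, 0, 0.4), 4)
  ens <- conformer_ensemble("z", coords, rep(0, 6), mol$elements,
                            bonds = mol$bonds)
  ref <- mol$coords
  al <- alignment_spec("a", c(1, 2, 3))
  g <- grid_spec(1.0)
  occ <- compute_gcods(list(ens), ref, al, g)
  per <- per_conformer_occupancy(ens, ref, al, g)
  avg <- colMeans(per)
  expect_setequal(colnames(occ), names(avg))
  expect_equal(unname(occ[1, names(avg)]), unname(avg), tolerance = 1e-12)
})
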