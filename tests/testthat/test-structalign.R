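test_that("identical and rigidly moved structures superpose to zero RMSD", {
  p <- toy_points(5)
  fit <- kabsch_superpose(p, p)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # rotate 90 degrees about z and translate
  q <- sweep(p %*% t(rotmat_z(90)), 2, c(3, -2, 5), `+`)
  fit2 <- kabsch_superpose(p, q)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the brute-force rotation-grid oracle", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    a <- toy_points(n)
    b <- a + matrix(rnorm(3 * n, 0, 0.15), ncol = 3)  # perturb all atoms
    b <- sweep(b %*% t(euler_rotation(runif(1, 0, 2 * pi),
                                      runif(1, 0, pi),
                                      runif(1, 0, 2 * pi))),
               2, runif(3, -4, 4), `+`)
    got <- kabsch_superpose(a, b)$rmsd
    oracle <- brute_force_rmsd(a, b)
    expect_lte(abs(got - oracle), 1e-3)
    expect_lte(got, oracle + 1e-9)  # least squares can never do worse
  }
})

test_that("RMSD is symmetric and invariant under rigid motion of either input", {
  set.seed(12)
  for (i in 1:10) {
    a <- toy_points(6) + matrix(rnorm(18, 0, 0.3), ncol = 3)
    b <- toy_points(6) + matrix(rnorm(18, 0, 0.3), ncol = 3)
    r1 <- kabsch_superpose(a, b)$rmsd
    expect_equal(kabsch_superpose(b, a)$rmsd, r1, tolerance = 1e-9)
    rig <- sweep(b %*% t(euler_rotation(0.3, 1.1, -0.7)), 2, c(1, 2, 3), `+`)
    expect_equal(kabsch_superpose(a, rig)$rmsd, r1, tolerance = 1e-9)
  }
})

test_that("degenerate point sets and reflections are handled explicitly", {
  line <- cbind(0:3, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  a <- toy_points(4)
  mirror <- a %*% diag(c(-1, 1, 1))
  fit <- kabsch_superpose(a, mirror)
  expect_true(fit$reflection_avoided)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)
})

test_that("plane anchoring puts the anchor plane on z = 0 with the stated frame", {
  set.seed(13)
  p <- toy_points(6)
  moved <- sweep(p %*% t(euler_rotation(0.9, 0.4, 2.2)), 2, c(5, -1, 2), `+`)
  out <- plane_anchor_align(moved, c(1, 2, 3))
  expect_equal(out[1, ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(out[2, 2:3], c(0, 0), tolerance = 1e-9)
  expect_gt(out[2, 1], 0)                       # second anchor on +x
  expect_equal(out[c(1, 2, 3), 3], rep(0, 3), tolerance = 1e-9)
  # an already-anchored structure is returned unchanged
  again <- plane_anchor_align(out, c(1, 2, 3))
  expect_equal(again, out, tolerance = 1e-9)
  expect_error(plane_anchor_align(cbind(0:2, 0, 0), c(1, 2, 3)), "collinear")
})

test_that("anchored structures differ by exactly the internal deformation", {
  # two copies related by a rigid motion anchor to identical coordinates
  p <- toy_points(6)
  q <- sweep(p %*% t(euler_rotation(1.2, 0.3, 0.8)), 2, c(-2, 4, 1), `+`)
  pa <- plane_anchor_align(p, c(1, 2, 3))
  qa <- plane_anchor_align(q, c(1, 2, 3))
  expect_equal(pa, qa, tolerance = 1e-9)
})

test_that("crystal-vs-minimum RMSD recovers the generator's known distortion", {
  ens0 <- tiny_ensemble()
  # zero-distortion copy: crystal identical to the minimum
  gm <- global_minimum(ens0)
  same <- compound_ensemble("H", list(
    gm,
    conformer_record("crystal", gm$total_energy + 0.01, 1, gm$coordinates,
                     "crystal_reference")), anchors = ens0$anchors)
  expect_equal(as.numeric(crystal_vs_minimum_rmsd(same)), 0,
               tolerance = 1e-9)
  # known phenyl-dihedral distortion + random rigid motion: anchored RMSD
  # equals the RMSD computed directly from the constructed coordinates
  tpl <- scaffold_template("Cl")
  angles <- c(20, 60, 110, 160)
  rmsds <- vapply(angles, function(th) {
    gm_c <- quinspec:::apply_torsions(tpl)
    cry <- quinspec:::apply_torsions(tpl, phenyl_deg = th)
    direct <- quinspec:::heavy_rmsd_direct(gm_c, cry)
    m <- as.matrix(cry[, 2:4]) %*% t(euler_rotation(0.5, 1.0, -0.3))
    cry[, 2:4] <- sweep(m, 2, c(2, -1, 3), `+`)
    ens <- compound_ensemble("Cl", list(
      conformer_record("gm", -100, 1, gm_c, "global_minimum"),
      conformer_record("crystal", -99.99, 1, cry, "crystal_reference")),
      anchors = tpl$anchors)
    got <- as.numeric(crystal_vs_minimum_rmsd(ens))
    expect_equal(got, direct, tolerance = 1e-9)
    got
  }, numeric(1))
  # larger built-in distortion => larger RMSD, and Kabsch never exceeds the
  # anchored residual
  expect_true(all(diff(rmsds) > 0))
})

test_that("kabsch protocol bounds the anchored one from below", {
  tpl <- scaffold_template("Br")
  gm_c <- quinspec:::apply_torsions(tpl)
  cry <- quinspec:::apply_torsions(tpl, phenyl_deg = 80)
  ens <- compound_ensemble("Br", list(
    conformer_record("gm", -100, 1, gm_c, "global_minimum"),
    conformer_record("crystal", -99.99, 1, cry, "crystal_reference")),
    anchors = tpl$anchors)
  anchored <- as.numeric(crystal_vs_minimum_rmsd(ens, method = "anchor"))
  kb <- as.numeric(crystal_vs_minimum_rmsd(ens, method = "kabsch"))
  expect_lte(kb, anchored + 1e-9)
})

test_that("missing crystal pose or mismatched atoms raise errors", {
  w <- water_coords()
  ens <- compound_ensemble("H", list(
    conformer_record("a", -1, 1, w, "global_minimum")))
  expect_error(crystal_vs_minimum_rmsd(ens), "no crystal_reference")
  ens2 <- compound_ensemble("H", list(
    conformer_record("a", -1, 1, w, "global_minimum"),
    conformer_record("c", 0, 1, w[c(2, 1, 3), ], "crystal_reference")))
  expect_error(crystal_vs_minimum_rmsd(ens2, method = "kabsch"),
               "mismatch")
})
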