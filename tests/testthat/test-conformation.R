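test_that("pseudorotation analysis inverts the generating formula", {
  ## independent oracle: generate the five ring torsions from (P, numax)
  ## with nu_j = numax cos(P + 144 (j - 2)), then invert
  for (P0 in c(18, 90, 162, 250, 340)) {
    nu <- 38 * cos((P0 + 144 * ((0:4) - 2)) * pi / 180)
    ph <- chiralhh:::as_phase(nu)
    expect_equal(ph$P, P0, tolerance = 1e-9)
    expect_equal(ph$numax, 38, tolerance = 1e-9)
    ## the invariant nu2 = numax cos(P)
    expect_equal(nu[3], ph$numax * cos(ph$P * pi / 180), tolerance = 1e-9)
  }
  ## flat ring: amplitude below the floor leaves P undefined
  ph <- chiralhh:::as_phase(rep(0, 5))
  expect_equal(ph$numax, 0)
  st <- fx_residue("C", P = 18)
  ps <- pseudorotation(st, "A", 1)
  expect_equal(ps$P, 18, tolerance = 1e-5)
  expect_equal(ps$numax, 38, tolerance = 1e-5)
})

test_that("parametric nucleotides hit their prescribed conformation", {
  for (code in c("A", "C", "G", "U")) {
    for (P0 in c(18, 99, 162)) {
      st <- fx_residue(code, P = P0, chi = -120)
      ps <- pseudorotation(st, "A", 1)
      expect_equal(ps$P, P0, tolerance = 1e-5)
      expect_equal(glycosidic_chi(st, "A", 1), -120, tolerance = 1e-6)
      expect_equal(as.character(classify_residue_chirality(st, "A", 1)), "D")
    }
  }
})

test_that("pucker classes and conformer bins follow the N/S windows", {
  expect_equal(classify_pucker(18), list(class = "N", conformer = "C3'-endo"))
  expect_equal(classify_pucker(162), list(class = "S", conformer = "C2'-endo"))
  expect_equal(classify_pucker(90)$class, "other")
  expect_equal(classify_pucker(90)$conformer, "O4'-endo")
  expect_equal(classify_pucker(315)$class, "N")
  expect_equal(classify_pucker(314.9)$class, "other")
  expect_equal(classify_pucker(225 - 1e-9)$class, "S")
  expect_error(classify_pucker(NA_real_), "refused")
})

test_that("syn/anti classification uses the |chi| >= 90 rule", {
  expect_equal(classify_syn_anti(-158), "anti")
  expect_equal(classify_syn_anti(65), "syn")
  expect_equal(classify_syn_anti(90), "anti")   # boundary -> anti
  expect_equal(classify_syn_anti(-90), "anti")
  expect_equal(classify_syn_anti(89.9), "syn")
  expect_equal(classify_syn_anti(275), "syn")   # wraps to -85
})

test_that("backbone torsions report termini as absent and match the build", {
  d <- fx_duplex_a()
  bt <- backbone_torsions(d, "A")
  expect_true(is.na(bt$alpha[1]) && is.na(bt$beta[1]))  # free 5'-OH terminus
  expect_false(anyNA(bt$alpha[-1]))
  expect_true(is.na(bt$epsilon[nrow(bt)]) && is.na(bt$zeta[nrow(bt)]))
  ## gamma is the pinned A-form generator value for every residue
  expect_angle_equal(bt$gamma, rep(54, nrow(bt)), tol = 1e-6)
  ## mirrored chain: every defined angle negated (dihedral oracle)
  bm <- backbone_torsions(mirror_structure(d), "A")
  for (ang in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")) {
    expect_angle_equal(bm[[ang]], -bt[[ang]], tol = 1e-9)
  }
})

test_that("descriptors are invariant under rigid motion", {
  d <- fx_duplex_a()
  set.seed(3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- d
  coords(moved) <- chiralhh:::xform(coords(d), R, c(5, -3, 11))
  ta <- conformation_table(d); tb <- conformation_table(moved)
  for (ang in c("alpha", "gamma", "zeta", "chi", "P")) {
    expect_angle_equal(tb[[ang]], ta[[ang]], tol = 1e-9)
  }
})

test_that("ring torsions reconstruct from (P, numax) within the AS bound", {
  st <- fx_residue("U", P = 45)
  ps <- pseudorotation(st, "A", 1)
  rec <- ps$numax * cos((ps$P + 144 * ((0:4) - 2)) * pi / 180)
  expect_lt(max(abs(rec - ps$nu)), 1.5)
})

test_that("phosphate distance series behave at termini and match the forms", {
  d <- fx_duplex_a()
  expect_length(phosphate_distances(d, "A"), n_residues(d, "A") - 2)
  one <- fx_residue("G")
  expect_length(phosphate_distances(one, "A"), 0)
  b <- fx_duplex_b()
  expect_gt(mean(phosphate_distances(b, "A")), mean(phosphate_distances(d, "A")))
})
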