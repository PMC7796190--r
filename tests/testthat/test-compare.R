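rand_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 3), ncol = 3)
}

rand_rotation <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

test_that("Kabsch superposition recovers rigid transforms", {
  P <- rand_points(20, 1)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  R <- rand_rotation(2)
  Q <- chiralhh:::xform(P, R, c(4, -2, 9))
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_true(fit$proper)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  ## orthogonality
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-9)
  expect_error(kabsch_superpose(P, P[1:5, ]), "correspondence")
  expect_warning(kabsch_superpose(cbind(1:9, 2 * (1:9), 3 * (1:9)),
                                  cbind(1:9, 2 * (1:9), 3 * (1:9))),
                 "collinear")
})

test_that("reflection handling separates enantiomers", {
  P <- rand_points(25, 3)
  M <- P; M[, 3] <- -M[, 3]
  expect_lt(kabsch_superpose(P, M, allow_reflection = TRUE)$rmsd, 1e-9)
  fit <- kabsch_superpose(P, M, allow_reflection = FALSE)
  expect_gt(fit$rmsd, 0.1)
  expect_true(fit$proper)
  ## oracle equivalence: mirror-allowed fit = min(proper fit, proper fit
  ## against the mirriored target)
  for (seed in 4:8) {
    A <- rand_points(12, seed)
    B <- rand_points(12, seed + 100)
    Bm <- B; Bm[, 3] <- -Bm[, 3]
    r_refl <- kabsch_superpose(A, B, allow_reflection = TRUE)$rmsd
    r_min <- min(kabsch_superpose(A, B)$rmsd,
                 kabsch_superpose(A, Bm)$rmsd)
    expect_equal(r_refl, r_min, tolerance = 1e-9)
  }
})

test_that("fixed-correspondence RMSD is a metric", {
  for (seed in 1:5) {
    A <- rand_points(15, seed)
    B <- rand_points(15, seed + 50)
    C <- rand_points(15, seed + 90)
    dab <- chiralhh:::rmsd_xyz(A, B)
    dba <- chiralhh:::rmsd_xyz(B, A)
    dac <- chiralhh:::rmsd_xyz(A, C)
    dbc <- chiralhh:::rmsd_xyz(B, C)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("selection RMSD resolves named subsets and counts atoms", {
  sc <- fx_scaffold()
  r <- rmsd_selection(sc, sc, selection = list(chain = "S"))
  expect_equal(as.numeric(r), 0)
  expect_equal(attr(r, "n"), 289)
  r2 <- rmsd_selection(sc, sc, selection = list(chain = "R"))
  expect_equal(attr(r2, "n"), 711)
  p <- perturb(sc, 0.1, seed = 4)
  r3 <- rmsd_selection(sc, p, selection = list(chain = "S"))
  r4 <- rmsd_selection(sc, p, selection = list(chain = "S"))
  expect_identical(as.numeric(r3), as.numeric(r4))
  expect_error(rmsd_selection(sc, fx_duplex_a()), "selection error")
})

test_that("region RMSD series: zeros for identical/translated frames", {
  sc <- fx_scaffold()
  moved <- sc
  coords(moved) <- sweep(coords(sc), 2, -c(10, 5, 2))
  ens <- rna_ensemble(list(sc, sc, moved))
  regions <- pairing_regions(attr(sc, "pairing"))
  ser <- region_rmsd_series(ens, regions)
  expect_true(all(ser$rmsd < 1e-9))
  expect_setequal(unique(ser$region),
                  c("helix1", "helix2", "helix3", "core", "substrate",
                    "ribozyme", "all"))
  ## per-frame noise: series scales like sigma sqrt(3)
  frames <- lapply(1:12, function(s) perturb(sc, 0.15, seed = s))
  ens2 <- rna_ensemble(c(list(sc), frames))
  ser2 <- region_rmsd_series(ens2, list(all = NULL))
  expect_equal(mean(ser2$rmsd[ser2$frame > 1]), 0.15 * sqrt(3),
               tolerance = 0.05)
})

test_that("circular medians and quartiles match a brute-force oracle", {
  ## oracle: fine grid search for the minimizer of the mean circular
  ## absolute deviation
  brute_dev <- function(x, m) mean(abs(chiralhh:::wrap180(x - m)))
  set.seed(10)
  for (k in 1:8) {
    x <- chiralhh:::wrap180(rnorm(51, mean = sample(c(-170, 0, 90, 179), 1),
                                  sd = 20))
    med <- circular_median(x)
    grid <- seq(-179.95, 180, by = 0.05)
    expect_lte(brute_dev(x, med),
               min(vapply(grid, function(g) brute_dev(x, g), numeric(1))) + 1e-9)
    ## exact antisymmetry under negation of the data
    expect_equal(circular_median(-x), -med, tolerance = 1e-12)
  }
  ## wrap-around data: median near the +-180 seam, not near 0
  x <- c(rep(175, 5), rep(-175, 6))
  expect_gt(abs(circular_median(x)), 170)
  q <- chiralhh:::circular_quartiles(x)
  expect_lt(abs(chiralhh:::wrap180(q["q3"] - q["q1"])), 15)
})

test_that("conformer distributions propagate mirror symmetry", {
  d <- build_duplex("GC", helix_form("A"))
  spec <- ensemble_spec(n_models = 24, P_sd = 6, chi_sd = 6,
                        noise_sd = 0, seed = 21)
  ens <- generate_ensemble(d, spec)
  cd <- conformer_distribution(ens)
  ensm <- mirror_structure(ens)
  cdm <- conformer_distribution(ensm)
  expect_angle_equal(cdm$P_med, cd$P_med + 180, tol = 1e-6)
  expect_angle_equal(cdm$chi_med, -cd$chi_med, tol = 1e-6)
  expect_equal(cdm$frac_syn, cd$frac_syn)
  ## alternating N/S prescription is recovered as alternating S fractions
  d6 <- build_duplex("GACUGC", helix_form("A"))
  spec2 <- ensemble_spec(n_models = 30, P_mean = rep(c(18, 162), 6),
                         P_sd = 6, chi_sd = 4, noise_sd = 0, seed = 5)
  cd2 <- conformer_distribution(generate_ensemble(d6, spec2))
  expect_true(all(abs(cd2$frac_S - rep(c(0, 1), 6)) < 0.15))
})

test_that("angle-difference profiles vanish for identical structures", {
  d <- fx_duplex_a()
  prof <- torsion_difference_profile(d, d)
  dc <- as.matrix(prof[, grep("^d_", names(prof))])
  expect_lt(max(abs(dc), na.rm = TRUE), 1e-12)
  ## a vs mirror(a) re-mirrored: all zeros; directly: delta = 2 theta
  m <- mirror_structure(d)
  prof0 <- torsion_difference_profile(d, mirror_structure(m))
  expect_lt(max(abs(as.matrix(prof0[, grep("^d_", names(prof0))])),
                na.rm = TRUE), 1e-9)
  ta <- conformation_table(d)
  profm <- torsion_difference_profile(d, m)
  expect_angle_equal(profm$d_chi, 2 * ta$chi, tol = 1e-6)
  expect_error(torsion_difference_profile(d, build_duplex("GC", "A")),
               "topology mismatch")
})

test_that("circular summary reports full mirror symmetry for enantiomers", {
  d <- fx_duplex_a()
  cs <- circular_summary(list(dd = d, ll = mirror_structure(d)),
                         mirror_pairs = list(c("dd", "ll")))
  expect_equal(nrow(cs[cs$label == "dd", ]), n_residues(d))
  sym <- attr(cs, "symmetry")
  expect_equal(sym$verdict, "full symmetry")
})
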