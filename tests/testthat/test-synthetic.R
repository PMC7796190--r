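test_that("generated duplexes satisfy all construction contracts", {
  for (fm in c("A", "B")) {
    form <- helix_form(fm)
    d <- build_duplex("GACUGC", form)
    expect_equal(sequence_of(d, "B"), reverse_complement("GACUGC"))
    ## every intended pair detected, all homochiral
    det <- detect_wc_pairs_3d(d)
    expect_equal(nrow(det), 6)
    expect_true(all(det$chirality_class == "homochiral"))
    ## pucker class equals the form target for every residue
    ct <- conformation_table(d)
    expect_true(all(ct$conformer == form$target_pucker))
    expect_equal(validate_chirality(d)$verdict, "all-D")
  }
  expect_error(build_duplex("GAXU"), "sequence error")
  expect_error(build_duplex("G"), "length >= 2")
})

test_that("adjacent P-P distances hit the A/B-form fiber values", {
  da <- build_duplex("GACUGCAUGC", helix_form("A"))
  db <- build_duplex("GACUGCAUGC", helix_form("B"))
  ppa <- c(phosphate_distances(da, "A"), phosphate_distances(da, "B"))
  ppb <- c(phosphate_distances(db, "A"), phosphate_distances(db, "B"))
  expect_lt(abs(mean(ppa) - 5.9), 0.15)
  expect_lt(abs(mean(ppb) - 7.0), 0.15)
  ## two-pair duplex: both pairs detectable
  gc <- build_duplex("GC", helix_form("A"))
  expect_equal(nrow(detect_wc_pairs_3d(gc)), 2)
})

test_that("perturb is seeded, deterministic and scales as sigma sqrt(3)", {
  d <- fx_duplex_a()
  expect_identical(coords(perturb(d, 0, seed = 1)), coords(d))
  p1 <- perturb(d, 0.1, seed = 7)
  p2 <- perturb(d, 0.1, seed = 7)
  expect_identical(coords(p1), coords(p2))
  expect_false(identical(coords(p1), coords(perturb(d, 0.1, seed = 8))))
  ## Monte-Carlo: RMSD approx sigma sqrt(3) over many draws
  rms <- vapply(1:40, function(s) {
    chiralhh:::rmsd_xyz(coords(d), coords(perturb(d, 0.2, seed = s)))
  }, numeric(1))
  expect_equal(mean(rms), 0.2 * sqrt(3), tolerance = 0.02)
})

test_that("generate_ensemble is deterministic and honors degenerate specs", {
  d <- build_duplex("GC", helix_form("A"))
  spec0 <- ensemble_spec(n_models = 3, P_mean = 18, P_sd = 0,
                         chi_mean = -150, chi_sd = 0, noise_sd = 0, seed = 5)
  ens <- generate_ensemble(d, spec0)
  expect_length(ens, 3)
  ct <- conformation_table(ens)
  expect_lt(max(abs(ct$P - 18)), 1)
  expect_lt(max(abs(ct$chi + 150)), 1e-6)
  ## identical seed => identical structures
  ens2 <- generate_ensemble(d, spec0)
  expect_identical(lapply(ens$models, coords), lapply(ens2$models, coords))
  spec1 <- ensemble_spec(n_models = 2, P_sd = 5, chi_sd = 5,
                         noise_sd = 0.01, seed = 9)
  e1 <- generate_ensemble(d, spec1)
  e2 <- generate_ensemble(d, spec1)
  expect_identical(coords(e1$models[[2]]), coords(e2$models[[2]]))
})

test_that("ensemble spec round-trips through JSON config", {
  spec <- ensemble_spec(n_models = 10, P_mean = 150, P_sd = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(spec), f, auto_unbox = TRUE, null = "null")
  back <- read_ensemble_spec(f)
  expect_equal(back$n_models, 10L)
  expect_equal(back$P_mean, 150)
  expect_equal(back$seed, 3L)
})

test_that("hammerhead scaffold meets its topological contracts", {
  sc <- fx_scaffold()
  expect_equal(n_residues(sc, "R") + n_residues(sc, "S"), 47)
  expect_equal(nrow(sc$atoms), 1000)
  ## helix-2 pairs pass 3D detection
  det <- detect_wc_pairs_3d(sc)
  mp <- chiralhh:::match_pairs(det, attr(sc, "pairing"))
  expect_true(all(mp$detected[mp$helix == "H2"]))
  expect_equal(sum(mp$helix == "H2"), 4)
  ## all 47 residues D
  v <- validate_chirality(sc)
  expect_equal(sum(v$residues$chirality == "D"), 47)
  ## clash floor among non-bonded residues
  xyz <- coords(sc)
  key <- paste(sc$atoms$chain, sc$atoms$resi)
  d2 <- as.matrix(dist(xyz))
  near <- outer(key, key, "==") |
    outer(paste(sc$atoms$chain, sc$atoms$resi + 1), key, "==") |
    outer(paste(sc$atoms$chain, sc$atoms$resi - 1), key, "==")
  expect_gt(min(d2[!near]), 2.4)
})

test_that("scaffold generation is deterministic", {
  sc1 <- build_hammerhead_scaffold(RIBOZYME_SEQ, SUBSTRATE_SEQ)
  expect_identical(coords(sc1), coords(fx_scaffold()))
})
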