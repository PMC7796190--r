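test_that("GUC|N scanning finds cleavage sites", {
  expect_equal(find_cleavage_sites(SUBSTRATE_SEQ), 9L)
  expect_equal(find_cleavage_sites("AAAA"), integer(0))
  ## brute-force oracle over all windows
  brute <- function(s) {
    ch <- strsplit(s, "")[[1]]
    which(vapply(seq_along(ch), function(i) {
      i >= 3 && i < length(ch) && all(ch[(i - 2):i] == c("G", "U", "C"))
    }, logical(1)))
  }
  for (s in c("GUCGUCA", "GUC", "GGUCC", "UGUCAGUCAGUCA", SUBSTRATE_SEQ)) {
    expect_equal(find_cleavage_sites(s), as.integer(brute(s)))
  }
  expect_equal(find_cleavage_sites("GUCGUCA"), c(3L, 6L))
})

test_that("hammerhead pairing reproduces the three-helix topology", {
  pm <- fx_pairing()
  h1 <- pm$pairs[pm$pairs$helix == "H1", ]
  h3 <- pm$pairs[pm$pairs$helix == "H3", ]
  h2 <- pm$pairs[pm$pairs$helix == "H2", ]
  ## H1: substrate 10..14 against ribozyme 5..1
  expect_equal(sort(h1$resi2), 10:14)
  expect_equal(sort(h1$resi1), 1:5)
  expect_equal(nrow(h1), 5)
  ## H3: substrate 3..8 against ribozyme 33..28
  expect_equal(sort(h3$resi2), 3:8)
  expect_equal(sort(h3$resi1), 28:33)
  expect_equal(nrow(h3), 6)
  ## H2: 4 G-C pairs closing a GAAA loop
  expect_equal(nrow(h2), 4)
  expect_true(all(h2$type == "G-C"))
  loop <- paste(strsplit(RIBOZYME_SEQ, "")[[1]][pm$loop], collapse = "")
  expect_equal(loop, "GAAA")
  expect_equal(pm$cleavage_site, 9L)
  ## unpaired set: no residue in two pairs
  refs <- c(paste(pm$pairs$chain1, pm$pairs$resi1),
            paste(pm$pairs$chain2, pm$pairs$resi2))
  expect_false(any(duplicated(refs)))
})

test_that("pairing errors name the offending positions", {
  ## substrate A14U breaks the helix-1 anchor
  mut <- sub("A$", "U", SUBSTRATE_SEQ)
  expect_error(hammerhead_pairing(RIBOZYME_SEQ, mut), "14")
  expect_error(hammerhead_pairing(RIBOZYME_SEQ, "CUUCAAGACCGCCA"),
               "exactly one GUC")
  expect_error(hammerhead_pairing(RIBOZYME_SEQ, "CGUCGUCAUGGCCA"),
               "exactly one GUC")
})

test_that("pairing is chirality-agnostic sequence logic", {
  ## the map depends only on the sequences, so it is identical whatever
  ## chirality metadata the strands will carry
  pm1 <- hammerhead_pairing(RIBOZYME_SEQ, SUBSTRATE_SEQ)
  pm2 <- hammerhead_pairing(RIBOZYME_SEQ, SUBSTRATE_SEQ, chains = c("R", "S"))
  expect_identical(pm1$pairs, pm2$pairs)
})

test_that("dot-bracket export is balanced and two-chain", {
  db <- pairing_to_dotbracket(fx_pairing())
  parts <- strsplit(db, "&")[[1]]
  expect_equal(nchar(parts[1]), nchar(RIBOZYME_SEQ))
  expect_equal(nchar(parts[2]), nchar(SUBSTRATE_SEQ))
  expect_equal(sum(strsplit(db, "")[[1]] == "("),
               sum(strsplit(db, "")[[1]] == ")"))
})

test_that("template heavy-atom accounting matches built structures", {
  expect_equal(count_heavy_atoms(SUBSTRATE_SEQ), 289)
  expect_equal(count_heavy_atoms(RIBOZYME_SEQ), 711)
  expect_equal(count_heavy_atoms(c(RIBOZYME_SEQ, SUBSTRATE_SEQ)), 1000)
  ## single G with a 5'-phosphate: 11 base + 12 backbone
  expect_equal(count_heavy_atoms("G", five_prime_phosphate = TRUE), 23)
  ## literal count of any built structure equals the template count
  sc <- fx_scaffold()
  expect_equal(nrow(sc$atoms), 1000)
  expect_equal(sum(sc$atoms$chain == "S"), 289)
  expect_equal(sum(sc$atoms$chain == "R"), 711)
  d <- build_duplex("GC", helix_form("A"),
                    five_prime_phosphate = c(TRUE, FALSE))
  expect_equal(nrow(d$atoms), count_heavy_atoms(c("GC", "GC"),
                                                c(TRUE, FALSE)))
})

test_that("3D Watson-Crick detection responds to geometry", {
  d <- build_duplex("GCGCGC", helix_form("A"))
  det <- detect_wc_pairs_3d(d)
  expect_equal(nrow(det), 6)
  expect_true(all(det$chirality_class == "homochiral"))
  ## strands 20 A apart: nothing detected
  far <- d
  sel <- far$atoms$chain == "B"
  far$atoms[sel, "x"] <- far$atoms[sel, "x"] + 20
  expect_equal(nrow(detect_wc_pairs_3d(far)), 0)
})

test_that("strand enantiomerization anchors bases and flips labels", {
  sc <- fx_scaffold()
  ## before refinement: per-residue base displacement is numerically zero
  het0 <- build_heterochiral(sc, "S", refine = FALSE)
  for (ri in c(1, 7, 14)) {
    code <- SUBSTRATE_SEQ
    base <- chiralhh:::BASE_ATOMS[[substr(code, ri, ri)]]
    a0 <- chiralhh:::residue_xyz(sc, "S", ri, base)
    a1 <- chiralhh:::residue_xyz(het0, "S", ri, base)
    expect_lt(chiralhh:::rmsd_xyz(a0, a1), 0.1)
  }
  expect_equal(validate_chirality(het0)$verdict, "mixed")
  ## with refinement: mixed verdict, H1/H3 heterochiral, H2 homochiral
  het <- fx_heterochiral()
  expect_equal(validate_chirality(het)$verdict, "mixed")
  det <- detect_wc_pairs_3d(het)
  mp <- chiralhh:::match_pairs(det, attr(sc, "pairing"))
  expect_true(all(mp$detected))
  cls <- merge(mp, det,
               by = c("chain1", "resi1", "chain2", "resi2"))
  expect_true(all(cls$chirality_class[cls$helix %in% c("H1", "H3")] ==
                    "heterochiral"))
  expect_true(all(cls$chirality_class[cls$helix == "H2"] == "homochiral"))
  ## applying the operation twice restores the all-D verdict
  het2 <- build_heterochiral(het, "S")
  expect_equal(validate_chirality(het2)$verdict, "all-D")
  expect_error(build_heterochiral(fx_duplex_a(), "A"), "pairing")
})

test_that("restrained refinement is monotone, convergent and guarded", {
  d <- build_duplex("GCGC", helix_form("A"))
  det <- detect_wc_pairs_3d(d)
  pm <- list(pairs = cbind(det[, c("chain1", "resi1", "resn1",
                                   "chain2", "resi2", "resn2", "type")],
                           helix = "H1"),
             chains = c("A", "B"))
  ref <- restrained_refine(d, pm, refinement_settings(steps = 60))
  expect_true(all(diff(ref$trace) <= 1e-9))
  ## 0 steps: identity
  ref0 <- restrained_refine(d, pm, refinement_settings(steps = 0))
  expect_identical(coords(ref0$structure), coords(d))
  ## idempotence at a converged structure
  conv <- restrained_refine(d, pm, refinement_settings(steps = 3000,
                                                       tol = 1e-12))
  again <- restrained_refine(conv$structure, pm,
                             refinement_settings(steps = 100))
  expect_lt(chiralhh:::rmsd_xyz(coords(again$structure),
                                coords(conv$structure)), 0.02)
  expect_lt(abs(utils::tail(again$trace, 1) - utils::tail(conv$trace, 1)),
            0.01 * max(1, utils::tail(conv$trace, 1)))
})

test_that("a stretched Watson-Crick contact relaxes to the 2.9 A target", {
  ## two unlinked paired residues: a single-restraint relaxation
  d <- build_duplex("GC", helix_form("A"))
  det <- detect_wc_pairs_3d(d)
  pm <- list(pairs = cbind(det[, c("chain1", "resi1", "resn1",
                                   "chain2", "resi2", "resn2", "type")],
                           helix = "H1"),
             chains = c("A", "B"))
  ## pull the B strand 0.6 A along the first H-bond direction
  g <- chiralhh:::residue_xyz(d, "A", 1, "N1")
  c3 <- chiralhh:::residue_xyz(d, "B", 2, "N3")
  dir <- chiralhh:::unit(c3[1, ] - g[1, ])
  sel <- d$atoms$chain == "B"
  d$atoms[sel, c("x", "y", "z")] <-
    sweep(as.matrix(d$atoms[sel, c("x", "y", "z")]), 2, -0.6 * dir)
  stretched <- max(detect_wc_pairs_3d(d, dmax = 99)$max_hbond)
  expect_gt(stretched, 3.3)
  ref <- restrained_refine(d, pm, refinement_settings(steps = 500))
  relaxed <- detect_wc_pairs_3d(ref$structure, dmax = 99)
  relaxed <- merge(relaxed, pm$pairs[, c("chain1", "resi1", "chain2", "resi2")])
  expect_equal(nrow(relaxed), 2)
  ## the pair geometry itself carries ~0.04 A residual, so allow slightly
  ## more than the pure single-restraint bound
  expect_lt(max(abs(relaxed$max_hbond - 2.9)), 0.08)
})
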