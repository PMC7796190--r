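ff_fixture <- function() {
  f <- withr::local_tempfile(fileext = ".frcmod", .local_envir = parent.frame())
  writeLines(c(
    "test parameters",
    "DIHE",
    "CT-OS-CT-N* 1 1.05 30.7 3",
    "OS-CT-CT-OH 1 0.30 0 2",
    "",
    "IMPROPER",
    "X-X-N*-CT 1.1 180 2",
    "CT-CT-CT-OS harm 25 35.2"), f)
  f
}

test_that("frcmod-like files parse, write and re-parse as a fixed point", {
  ps <- parse_parameters(ff_fixture())
  expect_equal(nrow(ps$torsions), 2)
  expect_equal(nrow(ps$impropers), 2)
  expect_equal(ps$torsions$phase, c(30.7, 0))
  expect_equal(ps$impropers$form, c("periodic", "harmonic"))
  expect_equal(ps$label, "D")
  f2 <- withr::local_tempfile(fileext = ".frcmod")
  write_parameters(ps, f2)
  ps2 <- parse_parameters(f2)
  expect_equal(ps2$torsions, ps$torsions)
  expect_equal(ps2$impropers, ps$impropers)
  ## malformed input
  f3 <- withr::local_tempfile(fileext = ".frcmod")
  writeLines(c("DIHE", "CT-OS-CT-N* 1 xx 30.7 3"), f3)
  expect_error(parse_parameters(f3), "line 2")
  writeLines(c("CT-OS-CT-N* 1 1.0 30.7 3"), f3)
  expect_error(parse_parameters(f3), "no section headers")
})

test_that("enantiomerization negates chirality-defining parameters, involution", {
  ps <- parse_parameters(ff_fixture())
  L <- enantiomerize(ps)
  expect_equal(L$label, "L")
  expect_equal(L$torsions$phase, c(360 - 30.7, 0))  # 0 is a fixed point
  expect_equal(L$torsions$k, ps$torsions$k)         # barriers unchanged
  expect_equal(L$impropers$phase, c(180, -35.2))    # 180 fixed; xi0 negated
  expect_equal(L$impropers$k, ps$impropers$k)
  back <- enantiomerize(L)
  expect_equal(back$torsions, ps$torsions)
  expect_equal(back$impropers, ps$impropers)
  expect_equal(back$label, "D")
})

test_that("torsion energy matches the closed form on a single term", {
  ## one proper term k=1, n=1, delta=0 evaluated at phi = 180 and 0
  f <- withr::local_tempfile(fileext = ".frcmod")
  writeLines(c("DIHE", "A-B-C-D 1 1.0 0 1", "IMPROPER"), f)
  ps <- parse_parameters(f)
  mk <- function(p4) {
    rna_structure(data.frame(
      chain = "A", resi = 1L, resn = "G",
      name = c("P", "OP1", "OP2", "O5'"), elem = "X",
      x = c(0, 0, 1, p4[1]), y = c(1, 0, 0, p4[2]), z = c(0, 0, 0, p4[3])))
  }
  quads <- data.frame(chain1 = "A", resi1 = 1L, name1 = "P",
                      chain2 = "A", resi2 = 1L, name2 = "OP1",
                      chain3 = "A", resi3 = 1L, name3 = "OP2",
                      chain4 = "A", resi4 = 1L, name4 = "O5'")
  asg <- torsion_assignment(quads, "torsion", 1L)
  expect_equal(torsion_energy(mk(c(1, -1, 0)), ps, asg), 0, tolerance = 1e-12)
  expect_equal(torsion_energy(mk(c(1, 1, 0)), ps, asg), 2, tolerance = 1e-12)
  ## unassigned quadruple
  bad <- asg; bad$name4 <- "O3'"
  expect_error(torsion_energy(mk(c(1, 1, 0)), ps, bad), "assignment error")
})

test_that("energy is invariant under mirror + enantiomerization, not without", {
  d <- fx_duplex_a()
  quads <- chiralhh:::structure_torsion_quads(d)
  f <- withr::local_tempfile(fileext = ".frcmod")
  writeLines(c(
    "DIHE",
    "A-A-A-A 1 1.4 30.7 3",
    "B-B-B-B 2 0.9 251.3 2",
    "C-C-C-C 1 2.0 180 1",
    "IMPROPER",
    "X-X-A-B 1.1 17 2",
    "X-X-C-D harm 20 35.2"), f)
  ps <- parse_parameters(f)
  n <- nrow(quads)
  kind <- rep(c("torsion", "torsion", "torsion", "improper", "improper"),
              length.out = n)
  term <- rep(c(1L, 2L, 3L, 1L, 2L), length.out = n)
  asg <- torsion_assignment(quads, kind, term)
  E_D <- torsion_energy(d, ps, asg)
  E_mirror <- torsion_energy(mirror_structure(d), enantiomerize(ps), asg)
  expect_equal(E_mirror, E_D, tolerance = 1e-9)
  ## D parameters on the mirrored (L) structure are NOT invariant: the
  ## fixture includes phases outside {0, 180}
  E_wrong <- torsion_energy(mirror_structure(d), ps, asg)
  expect_gt(abs(E_wrong - E_D), 1e-3)
})
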