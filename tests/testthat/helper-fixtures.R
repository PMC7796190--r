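## Shared fixtures, built once per test run and memoized.

RIBOZYME_SEQ <- "UGGCGCUGAUGAGGCCGAAAGGCCGAAACUUGA"
SUBSTRATE_SEQ <- "CUUCAAGUCCGCCA"

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

fx_duplex_a <- function() memo("duplex_a", build_duplex("GACUGC", helix_form("A")))

fx_duplex_b <- function() memo("duplex_b", build_duplex("GACUGC", helix_form("B")))

fx_pairing <- function() {
  memo("pairing", hammerhead_pairing(RIBOZYME_SEQ, SUBSTRATE_SEQ))
}

fx_scaffold <- function() {
  memo("scaffold",
       build_hammerhead_scaffold(RIBOZYME_SEQ, SUBSTRATE_SEQ, fx_pairing()))
}

fx_heterochiral <- function() {
  memo("heterochiral", build_heterochiral(fx_scaffold(), "S"))
}

## a single built residue wrapped as a structure
fx_residue <- function(code = "G", ...) {
  rna_structure(chiralhh:::residue_df("A", 1L, code,
                                      build_nucleotide(code, ...)))
}

expect_angle_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(chiralhh:::wrap180(a - b)), na.rm = TRUE), tol)
}
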