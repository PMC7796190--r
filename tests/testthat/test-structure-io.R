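test_that("PDB write/read round-trip preserves topology and coordinates", {
  d <- fx_duplex_a()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, f)
  ## single structure: no MODEL records
  expect_false(any(grepl("^MODEL", readLines(f))))
  ens <- read_pdb(f)
  expect_s3_class(ens, "rna_ensemble")
  expect_length(ens, 1)
  back <- ens$models[[1]]
  expect_equal(back$atoms$name, d$atoms$name)
  expect_equal(back$atoms$resn, d$atoms$resn)
  expect_equal(back$atoms$resi, d$atoms$resi)
  expect_lt(max(abs(coords(back) - coords(d))), 1e-3 + 1e-12)
  ## write-read-write is byte-idempotent
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("multi-model files get MODEL blocks and topology checking", {
  d <- fx_duplex_a()
  d2 <- perturb(d, 0.1, seed = 1)
  ens <- rna_ensemble(list(d, d2, d))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3)
  back <- read_pdb(f)
  expect_length(back, 3)
  expect_length(read_pdb(f, model_policy = "first"), 1)
  ## drop one atom from MODEL 2 -> ensemble error naming the offender
  lines <- readLines(f)
  bad <- which(grepl("^ATOM", lines) & grepl("O2'", lines) &
                 cumsum(grepl("^MODEL", lines)) == 2)[1]
  writeLines(lines[-bad], f)
  expect_error(read_pdb(f), "ensemble.*O2'|ensemble.*mismatch")
})

test_that("reader normalizes dialects, primes and drops hydrogens", {
  lines <- c(
    "ATOM      1  P   GUA A   7      11.000   2.000   3.000  1.00  0.00           P",
    "ATOM      2  O5* GUA A   7      12.000   2.500   3.100  1.00  0.00           O",
    "ATOM      3  H5' GUA A   7      12.500   2.100   3.500  1.00  0.00           H",
    "ATOM      4  N9  GUA A   7      13.000   3.000   3.200  1.00  0.00           N",
    "ATOM      5  C1′ GUA A   7      13.500   3.500   3.300  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  st <- read_pdb(f)$models[[1]]
  expect_equal(st$atoms$resn, rep("G", 4))       # hydrogens gone
  expect_equal(st$atoms$resi, rep(1L, 4))        # renumbered from 7
  expect_setequal(st$atoms$name, c("P", "O5'", "N9", "C1'"))
})

test_that("unknown residues are reported, bad coordinates are fatal", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P     A A   1       1.000   2.000   3.000  1.00  0.00           P",
    "ATOM      2  P   XXX A   2       1.000   2.000   3.000  1.00  0.00           P",
    "END"), f)
  expect_warning(read_pdb(f), "XXX")
  writeLines(c(
    "ATOM      1  P     A A   1       1.000   xxx     3.000  1.00  0.00           P",
    "END"), f)
  expect_error(read_pdb(f), "line 1")
})

test_that("sequences read off chains match the inputs", {
  sc <- fx_scaffold()
  expect_equal(sequence_of(sc, "S"), SUBSTRATE_SEQ)
  expect_equal(sequence_of(sc, "R"), RIBOZYME_SEQ)
  empty <- fx_duplex_a()
  expect_equal(sequence_of(empty, "Z"), "")
})

test_that("bio3d agrees with our reader on a written file", {
  skip_if_not_installed("bio3d")
  d <- fx_duplex_a()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, f)
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ref$atom), nrow(d$atoms))
  ## the written file carries PDB's 3-decimal precision
  expect_lt(max(abs(as.matrix(ref$atom[, c("x", "y", "z")]) - coords(d))),
            6e-4)
})

test_that("FASTA and plain sequence files are read", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">sub", SUBSTRATE_SEQ, ">rz", RIBOZYME_SEQ), f)
  seqs <- read_sequences(f)
  expect_equal(unname(seqs), c(SUBSTRATE_SEQ, RIBOZYME_SEQ))
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("cuuc aagu", "ccgcca"), f2)
  expect_equal(unname(read_sequences(f2)), SUBSTRATE_SEQ)
})
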