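test_that("degenerate and malformed inputs raise parse/format errors", {
  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(parseStructure(empty), "empty")
  expect_error(parseStructure(tempfile(fileext = ".pdb")),
               "does not exist")
  odd <- tempfile(fileext = ".xyz")
  writeLines("not a structure", odd)
  expect_error(parseStructure(odd), "format")
})

test_that("fixture dimer parses to the generator's own counts, in both formats", {
  fx <- makeAssembly(fixtureSpec("helix-dimer", seed = 3))
  d <- tempfile(); dir.create(d)
  pdbPath <- writeFixture(fx, d, "pdb")
  cifPath <- writeFixture(fx, d, "mmcif")

  a1 <- parseStructure(pdbPath)
  expect_equal(length(unique(atoms(a1)$chain)), 2)
  res1 <- unique(atoms(a1)[, c("chain", "resno", "insert")])
  expect_equal(nrow(res1), 60)

  a2 <- parseStructure(cifPath)
  expect_equal(nrow(atoms(a2)), nrow(atoms(a1)))
  expect_equal(sort(unique(atoms(a2)$chain)), sort(unique(atoms(a1)$chain)))
  expect_equal(nrow(unique(atoms(a2)[, c("chain", "resno")])), 60)

  # gzipped input parses identically
  gzPath <- file.path(d, "dimer.pdb.gz")
  con <- gzfile(gzPath, "wt")
  writeLines(readLines(pdbPath), con)
  close(con)
  a3 <- parseStructure(gzPath)
  expect_equal(nrow(atoms(a3)), nrow(atoms(a1)))
})

test_that("PDB round trip preserves chains, numbering, atom counts and metadata", {
  asm <- fixtureAssembly("dna-complex", seed = 2)
  out <- tempfile(fileext = ".pdb")
  writeAssemblyPDB(asm, out)
  back <- parseStructure(out)
  expect_equal(nrow(atoms(back)), nrow(atoms(asm)))
  expect_equal(sort(unique(atoms(back)$chain)),
               sort(unique(atoms(asm)$chain)))
  expect_equal(atoms(back)$resno, atoms(asm)$resno)
  expect_equal(expMethod(back), expMethod(asm))
  expect_equal(resolution(back), resolution(asm))
})

test_that("hydrogens are dropped and alt-locs reduced to one conformer", {
  lines <- c(
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.     1.50 ANGSTROMS.",
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       0.500   0.000   0.000  0.60 10.00           N",
    "ATOM      3  CA AALA A   1       1.500   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BALA A   1       2.000   0.000   0.000  0.50 10.00           C",
    "ATOM      5  C   ALA A   1       3.000   0.000   0.000  1.00 10.00           C",
    "ATOM      6  H   ALA A   1       4.000   0.000   0.000  1.00 10.00           H",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  asm <- parseStructure(f)
  a <- atoms(asm)
  expect_false(any(a$elesy %in% c("H", "D")))
  # highest occupancy wins (B for N); occupancy tie goes to altloc A (CA)
  expect_equal(sum(a$elety == "N"), 1)
  expect_equal(a$x[a$elety == "N"], 0.5)
  expect_equal(sum(a$elety == "CA"), 1)
  expect_equal(a$x[a$elety == "CA"], 1.5)
  # no duplicate (chain, resno, insert, atom name)
  expect_false(anyDuplicated(a[, c("chain", "resno", "insert",
                                   "elety")]) > 0)
  expect_equal(resolution(asm), 1.5)
})

test_that("radius assignment uses the shipped table, defaults with warning, idempotent", {
  asm <- fixtureAssembly("helix-dimer")
  a <- atoms(asm)
  expect_true(all(a$radius > 0))
  expect_equal(unique(a$radius[a$elesy == "C"]), 1.70)
  expect_equal(unique(a$radius[a$elesy == "N"]), 1.55)
  again <- assignRadii(asm)
  expect_identical(atoms(again)$radius, a$radius)

  odd <- asm
  odd@atoms$elesy[1] <- "XQ"
  expect_warning(odd <- assignRadii(odd), "default")
  expect_equal(atoms(odd)$radius[1], 1.80)
})

test_that("entry filter: non-NMR and strictly better than 4 A", {
  mk <- function(method, res) {
    asm <- fixtureAssembly("helix-dimer")
    asm@method <- method
    asm@resolution <- res
    asm
  }
  expect_true(entryPassesFilters(mk("X-RAY DIFFRACTION", 2.0)))
  expect_false(entryPassesFilters(mk("SOLUTION NMR", 2.0)))
  expect_false(entryPassesFilters(mk("X-RAY DIFFRACTION", 4.0)))
  expect_true(entryPassesFilters(mk("X-RAY DIFFRACTION", 3.999)))
  expect_false(suppressMessages(
    entryPassesFilters(mk("ELECTRON MICROSCOPY", NA_real_))))
  expect_true(entryPassesFilters(mk("ELECTRON MICROSCOPY", NA_real_),
                                 acceptMissingResolution = TRUE))
})
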