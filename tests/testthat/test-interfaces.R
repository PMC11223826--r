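test_that("the 100 A^2 interface filter is strict", {
  asm <- fixtureAssembly("helix-dimer", seed = 6)
  ents <- buildEntities(asm)
  mkMap <- function(area) {
    new("ResidueContactMap",
        contacts = data.frame(
          chain_a = "A", resno_a = 5L, insert_a = "", resid_a = "ALA",
          category_a = "standard-aa",
          chain_b = "B", resno_b = 5L, insert_b = "", resid_b = "ALA",
          category_b = "standard-aa", area = area,
          stringsAsFactors = FALSE),
        solvent = data.frame())
  }
  # patch the residue names so they exist in the assembly
  a <- atoms(asm)
  r5 <- unique(a[a$resno == 5, c("chain", "resid")])
  mk <- function(area) {
    m <- mkMap(area)
    m@contacts$resid_a <- r5$resid[r5$chain == "A"]
    m@contacts$resid_b <- r5$resid[r5$chain == "B"]
    m
  }
  expect_length(extractInterfaces(asm, ents, mk(100.0)), 0)  # "over" is strict
  expect_length(extractInterfaces(asm, ents, mk(100.01)), 1)
  expect_length(extractInterfaces(asm, ents, mk(99.9)), 0)
})

test_that("raising the area threshold never increases the interface count", {
  asm <- fixtureAssembly("helix-dimer", seed = 1)
  ents <- buildEntities(asm)
  rc <- fixtureContacts(asm)
  prev <- Inf
  for (thr in c(0, 50, 100, 200, 500)) {
    n <- length(extractInterfaces(asm, ents, rc, minArea = thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("a homotetramer of two identical dimers keeps one unique interface", {
  asm <- fixtureAssembly("homotetramer", seed = 2)
  ents <- buildEntities(asm)
  expect_equal(nrow(ents), 4)
  rc <- fixtureContacts(asm)
  ifs <- extractInterfaces(asm, ents, rc)
  expect_length(ifs, 1)
  # dedup keeps the largest-area representative deterministically
  again <- extractInterfaces(asm, ents, rc)
  expect_identical(names(ifs), names(again))
  expect_equal(totalArea(ifs[[1]]), totalArea(again[[1]]))
})

test_that("binding sites project protein sides only", {
  # protein-peptide: one site with the worked per-residue areas
  f <- tinyInterface(data.frame(pos_a = c(10, 11), pos_b = c(1, 1),
                                area = c(30, 45)),
                     itype = "PPep", kinds = c("protein", "peptide"))
  sites <- deriveBindingSites(list(f))
  expect_length(sites, 1)
  s <- sites[[1]]
  expect_equal(totalArea(s), 75)
  expect_equal(residueAreas(s)$area, c(30, 45))
  expect_identical(s@partnerKind, "peptide")

  # protein-protein: two sites, one per side
  fpp <- tinyInterface(data.frame(pos_a = 1:3, pos_b = c(5, 5, 6),
                                  area = c(10, 20, 30)))
  expect_length(deriveBindingSites(list(fpp)), 2)

  # protein-nucleic: the protein side only
  fna <- tinyInterface(data.frame(pos_a = 1:2, pos_b = 1:2,
                                  area = c(60, 50)),
                       itype = "PNA", kinds = c("protein", "nucleic"))
  sna <- deriveBindingSites(list(fna))
  expect_length(sna, 1)
  expect_identical(sna[[1]]@entityId, "E1")
})

test_that("interface area books against its per-side binding sites", {
  asm <- fixtureAssembly("helix-dimer", seed = 3)
  ents <- buildEntities(asm)
  ifs <- extractInterfaces(asm, ents, fixtureContacts(asm))
  sites <- deriveBindingSites(ifs)
  f <- ifs[[1]]
  for (s in sites)
    expect_equal(totalArea(s), totalArea(f), tolerance = 1e-9)
  # every site residue has positive area
  for (s in sites) expect_true(all(residueAreas(s)$area > 0))
})

test_that("bond annotation applies the geometric criteria", {
  # disulfide: SG-SG at the canonical 2.05 A bond length
  cys <- tinyAssembly(list(
    list(chain = "A", resno = 1, resid = "CYS", category = "standard-aa",
         atoms = list(N = c(-3, 0, 0), CA = c(-2, 0, 0), C = c(-2, 1, 0),
                      CB = c(-1, 0, 0), SG = c(0, 0, 0))),
    list(chain = "B", resno = 1, resid = "CYS", category = "standard-aa",
         atoms = list(N = c(5, 0, 0), CA = c(4, 0, 0), C = c(4, 1, 0),
                      CB = c(3, 0, 0), SG = c(2.05, 0, 0)))))
  f <- tinyInterface(data.frame(pos_a = 1, pos_b = 1, area = 10))
  f@contacts$resid_a <- f@contacts$resid_b <- "CYS"
  f@contacts$resno_a <- f@contacts$resno_b <- 1L
  ann <- annotateBonds(f, cys)
  expect_equal(ann@nDisulfides, 1L)

  # salt bridge: Lys NZ to Glu OE1 at 3.2 A
  sb <- tinyAssembly(list(
    list(chain = "A", resno = 1, resid = "LYS", category = "standard-aa",
         atoms = list(N = c(-4, 0, 0), CA = c(-3, 0, 0), C = c(-3, 1, 0),
                      CE = c(-1, 0, 0), NZ = c(0, 0, 0))),
    list(chain = "B", resno = 1, resid = "GLU", category = "standard-aa",
         atoms = list(N = c(7, 0, 0), CA = c(6, 0, 0), C = c(6, 1, 0),
                      CD = c(4.2, 0, 0), OE1 = c(3.2, 0, 0)))))
  ann2 <- annotateBonds(f, sb)
  expect_equal(ann2@nSaltBridges, 1L)

  # an all-alanine contact has no donors/acceptors/charges beyond the
  # backbone, placed too far here for any bond
  ala <- tinyAssembly(list(
    list(chain = "A", resno = 1, resid = "ALA", category = "standard-aa",
         atoms = list(N = c(-1, 0, 0), CA = c(0, 0, 0), C = c(1, 0, 0),
                      O = c(1, 1, 0), CB = c(0, -1, 0))),
    list(chain = "B", resno = 1, resid = "ALA", category = "standard-aa",
         atoms = list(N = c(5, 0, 0), CA = c(6, 0, 0), C = c(7, 0, 0),
                      O = c(7, 1, 0), CB = c(6, -1, 0)))))
  ann3 <- annotateBonds(f, ala)
  expect_equal(ann3@nHbonds, 0L)
  expect_equal(ann3@nSaltBridges, 0L)
  expect_equal(ann3@nDisulfides, 0L)
})

test_that("backbone hydrogen bond found with distance and angle criteria", {
  hb <- tinyAssembly(list(
    list(chain = "A", resno = 1, resid = "GLY", category = "standard-aa",
         atoms = list(N = c(0, 0, 0), CA = c(-1.2, 0.8, 0),
                      C = c(-2.2, 0, 0), O = c(-2.2, -1.2, 0))),
    list(chain = "B", resno = 1, resid = "GLY", category = "standard-aa",
         atoms = list(N = c(5, 0, 0), CA = c(6.2, 0.8, 0),
                      C = c(7.2, 0, 0), O = c(3.0, 0, 0)))))
  f <- tinyInterface(data.frame(pos_a = 1, pos_b = 1, area = 10))
  f@contacts$resid_a <- f@contacts$resid_b <- "GLY"
  f@contacts$resno_a <- f@contacts$resno_b <- 1L
  ann <- annotateBonds(f, hb)
  # donor N (A) at 3.0 A from acceptor O (B), CA-N-O angle > 90 deg
  expect_gte(ann@nHbonds, 1L)
})
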