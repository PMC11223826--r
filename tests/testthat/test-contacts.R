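# accuracy contract for tessellation areas: within 2% or 0.1 A^2,
# whichever is larger
areaTol <- function(a) pmax(0.02 * abs(a), 0.1)

test_that("two-ball face and single-ball solvent match the closed forms", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  res <- computeAtomContacts(co, radii = c(1.9, 1.9), probe = 1.4)
  expect_equal(nrow(res$contacts), 1)
  exact <- pi * ((1.9 + 1.4)^2 - 1.5^2)  # disk of radius^2 = 8.64
  expect_lt(abs(res$contacts$area - exact), areaTol(exact))

  one <- computeAtomContacts(matrix(0, 1, 3), radii = 1.9, probe = 1.4)
  expect_equal(nrow(one$contacts), 0)
  expect_lt(abs(one$solvent - 4 * pi * 3.3^2), areaTol(4 * pi * 3.3^2))

  # beyond expanded-sphere overlap there is no contact
  far <- computeAtomContacts(rbind(c(0, 0, 0), c(2 * 1.9 + 2 * 1.4 + 0.01,
                                                 0, 0)),
                             radii = c(1.9, 1.9), probe = 1.4,
                             solvent = FALSE)
  expect_equal(nrow(far$contacts), 0)
})

test_that("two-ball solvent area matches the analytic cap formula", {
  # sphere radius R cut by the radical plane at distance t from center:
  # removed cap area 2*pi*R*(R - t)
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  res <- computeAtomContacts(co, radii = c(1.9, 1.9), probe = 1.4,
                             nSphere = 10000)
  R <- 3.3
  expected <- 4 * pi * R^2 - 2 * pi * R * (R - 1.5)
  expect_lt(abs(res$solvent[1] - expected), areaTol(expected))
  expect_lt(abs(res$solvent[2] - expected), areaTol(expected))
})

test_that("coincident ball centers raise a degeneracy error naming the atoms", {
  co <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(computeAtomContacts(co, radii = c(1.9, 1.9)),
               "atoms 1 and 2.*coincident")
})

test_that("areas are symmetric, positive and invariant under rigid motion", {
  set.seed(11)
  co <- matrix(rnorm(3 * 25, sd = 3), ncol = 3)
  rad <- runif(25, 1.3, 2.0)
  res <- computeAtomContacts(co, radii = rad, solvent = FALSE)
  expect_true(all(res$contacts$area > 0))
  expect_true(all(res$contacts$i < res$contacts$j))

  # rotate + translate
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co2 <- co %*% t(Rz) + matrix(c(10, -5, 3), nrow(co), 3, byrow = TRUE)
  res2 <- computeAtomContacts(co2, radii = rad, solvent = FALSE)
  key <- function(r) paste(r$contacts$i, r$contacts$j)
  expect_setequal(key(res), key(res2))
  m <- match(key(res), key(res2))
  expect_true(all(abs(res$contacts$area - res2$contacts$area[m]) <
                    areaTol(res$contacts$area)))
})

test_that("pulling two balls apart shrinks their contact monotonically to zero", {
  prev <- Inf
  for (d in seq(1.0, 7.0, by = 0.5)) {
    res <- computeAtomContacts(rbind(c(0, 0, 0), c(d, 0, 0)),
                               radii = c(1.9, 1.9), solvent = FALSE)
    a <- if (nrow(res$contacts)) res$contacts$area else 0
    expect_lte(a, prev + 1e-9)
    prev <- a
  }
  expect_equal(prev, 0)
})

test_that("random instances agree with the Monte-Carlo power-sampling oracle", {
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(8:30, 1)
    co <- matrix(rnorm(3 * n, sd = 3.2), ncol = 3)
    rad <- runif(n, 1.2, 2.0)
    res <- computeAtomContacts(co, radii = rad, solvent = FALSE)
    expect_gt(nrow(res$contacts), 0)
    for (m in seq_len(nrow(res$contacts))) {
      mc <- mcFaceArea(co, rad, 1.4, res$contacts$i[m], res$contacts$j[m])
      tol <- areaTol(res$contacts$area[m]) + 3 * mc$se
      expect_lt(abs(res$contacts$area[m] - mc$area), tol)
    }
  }
})

test_that("residue aggregation sums atom areas and drops intra-residue pairs", {
  # two single-atom residues in contact
  asm <- tinyAssembly(list(
    list(chain = "A", resno = 1, resid = "UNK", category = "ligand",
         atoms = list(X1 = c(0, 0, 0))),
    list(chain = "B", resno = 1, resid = "UNK", category = "ligand",
         atoms = list(X1 = c(3, 0, 0)))))
  asm@atoms$radius <- 1.9
  ac <- computeAtomContacts(asm, solvent = FALSE)
  rc <- aggregateToResidues(asm, ac)
  expect_equal(nrow(contacts(rc)), 1)
  expect_equal(contacts(rc)$area, ac$contacts$area)

  # contacts only within one residue -> empty residue map
  intra <- tinyAssembly(list(
    list(chain = "A", resno = 1, resid = "UNK", category = "ligand",
         atoms = list(X1 = c(0, 0, 0), X2 = c(3, 0, 0)))))
  intra@atoms$radius <- 1.9
  rci <- aggregateToResidues(intra, computeAtomContacts(intra,
                                                        solvent = FALSE))
  expect_equal(nrow(contacts(rci)), 0)
})

test_that("aggregation conserves total inter-residue area on a fixture", {
  asm <- fixtureAssembly("helix-dimer", seed = 5)
  ac <- computeAtomContacts(asm, solvent = FALSE)
  rc <- aggregateToResidues(asm, ac)
  a <- atoms(asm)
  rid <- paste(a$chain, a$resno, a$insert)
  inter <- rid[ac$contacts$i] != rid[ac$contacts$j]
  expect_equal(sum(contacts(rc)$area), sum(ac$contacts$area[inter]),
               tolerance = 1e-9)
})
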