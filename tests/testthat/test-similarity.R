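idPair <- function(n = 10)
  list(left = identityCorrespondence(n), right = identityCorrespondence(n))

test_that("interface contact similarity reproduces the bounded-difference form", {
  A <- data.frame(pos_a = c(1, 2), pos_b = c(1, 2), area = c(10, 20))
  B <- data.frame(pos_a = c(1, 2, 3), pos_b = c(1, 2, 3),
                  area = c(10, 10, 10))
  # D(A->B) = 1 - 10/30, D(B->A) = 1 - 20/30, mean = 0.5
  expect_equal(interfaceContactSimilarity(A, B, idPair()), 0.5)

  # identity and disjoint extremes
  expect_equal(interfaceContactSimilarity(A, A, idPair()), 1.0)
  C <- data.frame(pos_a = c(7, 8), pos_b = c(7, 8), area = c(5, 5))
  expect_equal(interfaceContactSimilarity(A, C, idPair()), 0.0)

  # symmetry of the averaged score
  expect_equal(interfaceContactSimilarity(A, B, idPair()),
               interfaceContactSimilarity(B, A, idPair()))

  # empty side is undefined
  expect_error(interfaceContactSimilarity(A[0, ], B, idPair()), "empty")
})

test_that("binding-site residue-area similarity matches hand evaluation", {
  A <- data.frame(pos = c(1, 2), area = c(30, 45))
  B <- data.frame(pos = 1, area = 30)
  corr <- residueCorrespondence(1, 1)  # r2 unmatched
  # D(A->B) = 1 - 45/75 = 0.4, D(B->A) = 1 - 0/30 = 1, mean 0.7
  expect_equal(bindingSiteResidueAreaSimilarity(A, B, corr), 0.7)
  expect_equal(bindingSiteResidueAreaSimilarity(A, A,
                                                identityCorrespondence(2)),
               1.0)
  expect_error(bindingSiteResidueAreaSimilarity(A[0, ], B, corr), "empty")
})

test_that("similarity is invariant under uniform area scaling", {
  set.seed(31)
  A <- data.frame(pos_a = sample(1:8), pos_b = sample(1:8),
                  area = runif(8, 5, 50))
  B <- data.frame(pos_a = sample(1:8), pos_b = sample(1:8),
                  area = runif(8, 5, 50))
  s1 <- interfaceContactSimilarity(A, B, idPair())
  A2 <- A; A2$area <- A2$area * 7.3
  B2 <- B; B2$area <- B2$area * 7.3
  expect_equal(interfaceContactSimilarity(A2, B2, idPair()), s1)

  sa <- data.frame(pos = 1:5, area = runif(5, 1, 9))
  sb <- data.frame(pos = 1:5, area = runif(5, 1, 9))
  s2 <- bindingSiteResidueAreaSimilarity(sa, sb,
                                         identityCorrespondence(5))
  sa$area <- sa$area * 0.01; sb$area <- sb$area * 0.01
  expect_equal(bindingSiteResidueAreaSimilarity(
    sa, sb, identityCorrespondence(5)), s2)
})

test_that("patch measure tolerates contact rearrangement; contact measure does not", {
  # same per-residue marginals, permuted cross-pairings
  A <- data.frame(pos_a = c(1, 1, 2, 2), pos_b = c(1, 2, 1, 2),
                  area = c(10, 20, 20, 10))
  B <- data.frame(pos_a = c(1, 1, 2, 2), pos_b = c(1, 2, 1, 2),
                  area = c(20, 10, 10, 20))
  expect_equal(patchAreaSimilarity(A, B, idPair(2)), 1.0)
  expect_lt(interfaceContactSimilarity(A, B, idPair(2)), 1.0)

  # patch similarity is 1 whenever contact similarity is 1
  expect_equal(patchAreaSimilarity(A, A, idPair(2)), 1.0)
  # disjoint patches score 0
  C <- data.frame(pos_a = c(5, 6), pos_b = c(5, 6), area = c(10, 10))
  expect_equal(patchAreaSimilarity(A, C, idPair(6)), 0.0)

  # site mode scores residue-membership areas directly
  sa <- data.frame(pos = 1:2, area = c(30, 30))
  expect_equal(patchAreaSimilarity(sa, sa, identityCorrespondence(2),
                                   mode = "site"), 1.0)
})

test_that("multiple side-pairings: the best one is kept", {
  # A's sides swapped relative to B; only the swapped pairing matches
  A <- data.frame(pos_a = c(1, 2), pos_b = c(3, 4), area = c(10, 20))
  Bsw <- data.frame(pos_a = c(3, 4), pos_b = c(1, 2), area = c(10, 20))
  straight <- idPair(4)
  swapped <- list(left = identityCorrespondence(4),
                  right = identityCorrespondence(4))
  sw <- data.frame(pos_a = Bsw$pos_b, pos_b = Bsw$pos_a, area = Bsw$area)
  expect_equal(interfaceContactSimilarity(A, sw, list(straight)), 1.0)
  expect_lt(interfaceContactSimilarity(A, Bsw, list(straight)), 1.0)
  best <- max(interfaceContactSimilarity(A, Bsw, list(straight)),
              interfaceContactSimilarity(A, sw, list(swapped)))
  expect_equal(best, 1.0)
})

test_that("correspondences must be injective", {
  expect_error(residueCorrespondence(c(1, 1), c(2, 3)), "injective")
  expect_error(residueCorrespondence(c(1, 2), c(3, 3)), "injective")
})
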