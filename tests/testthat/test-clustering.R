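simMatrix <- function(n, entries, ids = as.character(seq_len(n))) {
  m <- diag(1, n)
  for (e in entries) m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
  rownames(m) <- colnames(m) <- ids
  m
}

test_that("Taylor-Butina reproduces the hand-traced example", {
  m <- simMatrix(5, list(c(1, 2, 0.8), c(1, 3, 0.6), c(2, 3, 0.7),
                         c(4, 5, 0.9)))
  m[m == 0] <- 0.1
  diag(m) <- 1
  cs <- taylorButina(m, 0.5)
  cl <- clusters(cs)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], c("1", "2", "3"))
  expect_setequal(cl[[2]], c("4", "5"))
  cent <- cs@members$item[cs@members$isCentroid]
  expect_setequal(cent, c("1", "4"))
  expect_length(singletons(cs), 0)
})

test_that("degenerate thresholds: everything together or all singletons", {
  m <- simMatrix(4, list(c(1, 2, 0.9), c(1, 3, 0.9), c(1, 4, 0.9),
                         c(2, 3, 0.9), c(2, 4, 0.9), c(3, 4, 0.9)))
  expect_length(clusters(taylorButina(m, 0.5)), 1)
  m2 <- simMatrix(4, list(c(1, 2, 0.3)))
  cs2 <- taylorButina(m2, 0.5)
  expect_length(clusters(cs2), 4)
  expect_length(singletons(cs2), 4)
})

test_that("matrix validation rejects malformed input", {
  m <- simMatrix(3, list(c(1, 2, 0.9)))
  bad <- m; bad[1, 2] <- 0.2
  expect_error(taylorButina(bad), "symmetric")
  bad2 <- m; bad2[1, 2] <- bad2[2, 1] <- 1.7
  expect_error(taylorButina(bad2), "\\[0, 1\\]")
  bad3 <- m; diag(bad3) <- 0.9
  expect_error(taylorButina(bad3), "diagonal")
})

test_that("agrees with the brute-force oracle on random matrices incl. ties", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    # coarse similarity grid provokes plenty of exact ties
    vals <- sample(seq(0, 1, by = 0.25), n * (n - 1) / 2, replace = TRUE)
    m <- diag(1, n)
    m[upper.tri(m)] <- vals
    m <- pmax(m, t(m))
    rownames(m) <- colnames(m) <- as.character(seq_len(n))
    cs <- taylorButina(m, 0.5)
    orc <- tbOracle(m, 0.5)
    got <- csCanonical(cs)
    expected <- tbOracleCanonical(orc, rownames(m))
    # same centroid assignment for every item
    expect_identical(unname(got[rownames(m)]), unname(expected))
    expect_setequal(singletons(cs), as.character(which(orc$singleton)))
    # invariants: partition + member similarity to centroid
    expect_setequal(names(got), rownames(m))
    mem <- cs@members
    for (k in seq_len(nrow(mem))) {
      if (!mem$isCentroid[k]) expect_gt(mem$simToCentroid[k], 0.5)
    }
  }
})

test_that("incremental updates keep old memberships and honour the threshold", {
  m <- simMatrix(4, list(c(1, 2, 0.9), c(3, 4, 0.8)))
  cs <- taylorButina(m, 0.5)
  big <- simMatrix(7, list(c(1, 2, 0.9), c(3, 4, 0.8), c(5, 1, 1.0),
                           c(6, 7, 0.7)))
  simFun <- function(a, b) big[a, b]

  up <- updateClusters(cs, c("5", "6", "7"), simFun)
  mem <- up@members
  # an exact copy of centroid "1" joins its cluster
  expect_equal(mem$cluster[mem$item == "5"],
               mem$cluster[mem$item == "1"])
  # dissimilar-to-centroids items cluster among themselves
  expect_equal(mem$cluster[mem$item == "6"], mem$cluster[mem$item == "7"])
  expect_false(mem$cluster[mem$item == "6"] %in%
                 mem$cluster[mem$item %in% c("1", "3")])
  # old memberships unchanged
  old <- cs@members
  for (it in old$item)
    expect_equal(mem$isCentroid[mem$item == it],
                 old$isCentroid[old$item == it])
  expect_error(updateClusters(cs, "1", simFun), "overlap")
})

test_that("batch vs incremental: assigned centroid similarity stays above threshold", {
  set.seed(61)
  for (rep in 1:20) {
    n <- 8
    m <- diag(1, n)
    v <- runif(n * (n - 1) / 2)
    m[upper.tri(m)] <- v
    m <- pmax(m, t(m))
    ids <- as.character(seq_len(n))
    rownames(m) <- colnames(m) <- ids
    batch <- taylorButina(m, 0.5)
    first <- taylorButina(m[1:5, 1:5], 0.5)
    incr <- updateClusters(first, ids[6:8], function(a, b) m[a, b])
    for (cs in list(batch, incr)) {
      mem <- cs@members
      nonCent <- mem[!mem$isCentroid, , drop = FALSE]
      if (nrow(nonCent)) expect_true(all(nonCent$simToCentroid > 0.5))
      expect_setequal(mem$item[mem$cluster %in%
                                 mem$cluster[mem$isCentroid]], mem$item)
    }
  }
})

test_that("stringency levels separate and merge fixtures as constructed", {
  # homodimer plus a 60%-identity mutant homodimer with identical geometry:
  # different clusters at the identical level, one cluster at high
  baseSeq <- makeAssembly(fixtureSpec("helix-dimer", seed = 8))$truth$sequence
  mutSeq <- makeMutantSeries(baseSeq, 0.6, seed = 9)[[1]]
  mk <- function(id, seqn) {
    fx <- makeAssembly(fixtureSpec("helix-dimer", seed = 8,
                                   sequence = seqn))
    asm <- suppressWarnings(assignRadii(fx$assembly))
    asm@entryId <- id
    ents <- buildEntities(asm)
    rc <- fixtureContacts(asm)
    f <- extractInterfaces(asm, ents, rc)[[1]]
    f@entityA <- paste(id, f@entityA, sep = ".")
    f@entityB <- paste(id, f@entityB, sep = ".")
    list(iface = stats::setNames(list(f), f@id),
         seqs = stats::setNames(rep(seqn, 2),
                                paste(id, c("E1", "E2"), sep = ".")))
  }
  x1 <- mk("base", baseSeq)
  x2 <- mk("mut", mutSeq)
  seqs <- c(x1$seqs, x2$seqs)
  cl95 <- clusterSequences(seqs, 0.95)
  cl40 <- clusterSequences(seqs, 0.40)
  msas95 <- lapply(cl95, buildMsa, seqs = seqs)
  msas40 <- lapply(cl40, buildMsa, seqs = seqs)
  items <- c(x1$iface, x2$iface)
  res <- clusterAtLevels(items, "interface", cl95, cl40, msas95, msas40)
  nClusters <- function(cs) length(unique(cs@members$cluster))
  expect_equal(nClusters(res$identical), 2)
  expect_equal(nClusters(res$high), 1)
  expect_equal(nClusters(res$similar), 1)

  # sequence-identical interfaces with identical contacts always
  # co-cluster within the 40% pre-group
  x3 <- mk("copy", baseSeq)
  seqs2 <- c(seqs, x3$seqs)
  cl95b <- clusterSequences(seqs2, 0.95)
  cl40b <- clusterSequences(seqs2, 0.40)
  res2 <- clusterAtLevels(c(items, x3$iface), "interface", cl95b, cl40b,
                          lapply(cl95b, buildMsa, seqs = seqs2),
                          lapply(cl40b, buildMsa, seqs = seqs2))
  m <- res2$high@members
  expect_equal(m$cluster[m$item == names(x1$iface)],
               m$cluster[m$item == names(x3$iface)])
})
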