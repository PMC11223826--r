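test_that("identity uses the shorter-sequence denominator", {
  a <- "ACDEFGHIKL"
  expect_equal(seqIdentity(a, a), 1.0)
  # half-identical pair of equal length
  b <- "ACDEFWWWWW"
  expect_equal(seqIdentity(a, b), 0.5, tolerance = 1e-6)
  # a perfect substring scores 1 against the longer sequence
  expect_equal(seqIdentity("ACDEF", a), 1.0)
})

test_that("greedy clustering respects the threshold and input degeneracies", {
  expect_error(clusterSequences(character(0), 0.4), "no sequences")

  two <- c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKL")
  expect_length(clusterSequences(two, 0.95), 1)
  expect_length(clusterSequences(two, 0.40), 1)

  half <- c(s1 = "ACDEFGHIKLMNPQRSTVWY", s2 = "ACDEFGHIKLWWWWWWWWWW")
  expect_length(clusterSequences(half, 0.40), 1)   # 50% >= 40%
  expect_length(clusterSequences(half, 0.95), 2)

  set.seed(41)
  rnd <- vapply(1:6, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                 replace = TRUE), collapse = ""), "")
  names(rnd) <- paste0("r", 1:6)
  cl <- clusterSequences(rnd, 0.40)
  expect_length(cl, 6)  # unrelated randoms stay singletons

  # partition + identity-to-representative invariant
  mut <- makeMutantSeries(rnd[[1]], c(0.95, 0.9, 0.5), seed = 7)
  seqs <- c(rnd, stats::setNames(mut, paste0("m", seq_along(mut))))
  cl <- clusterSequences(seqs, 0.40)
  tab <- seqClusterTable(cl)
  expect_setequal(tab$id, names(seqs))
  expect_false(anyDuplicated(tab$id) > 0)
  for (c in cl)
    for (m in c$members)
      expect_gte(seqIdentity(seqs[[m]], seqs[[c$representative]]), 0.40)
})

test_that("center-star MSA handles singletons, duplicates and one deletion", {
  seqs <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDFGHIKL")
  single <- list(representative = "a", members = "a")
  expect_identical(unname(buildMsa(single, seqs)), "ACDEFGHIKL")

  dup <- list(representative = "a", members = c("a", "b"))
  msa <- buildMsa(dup, seqs)
  expect_identical(unname(msa), c("ACDEFGHIKL", "ACDEFGHIKL"))

  del <- list(representative = "a", members = c("a", "c"))
  msa <- buildMsa(del, seqs)
  expect_equal(nchar(msa[["a"]]), 10)
  expect_equal(sum(strsplit(msa[["c"]], "")[[1]] == "-"), 1)
  # degapping recovers the member sequences
  expect_identical(gsub("-", "", msa[["c"]]), seqs[["c"]])
  expect_identical(gsub("-", "", msa[["a"]]), seqs[["a"]])
})

test_that("residue mapping reads MSA columns and is involutive", {
  msa <- c(x = "AC-D", y = "ACED")
  corr <- mapResidues(msa, "x", "y")
  expect_equal(corr$from, c(1, 2, 3))
  expect_equal(corr$to, c(1, 2, 4))

  # identity over all residues when mapping a member to itself
  self <- mapResidues(msa, "y", "y")
  expect_equal(self$from, 1:4)
  expect_equal(self$to, 1:4)

  # involution: map(a,b) is the inverse of map(b,a)
  inv <- mapResidues(msa, "y", "x")
  expect_equal(inv$from, corr$to)
  expect_equal(inv$to, corr$from)

  # disjoint gap patterns give an empty correspondence
  gappy <- c(p = "AB--", q = "--CD")
  expect_equal(nrow(mapResidues(gappy, "p", "q")), 0)

  expect_error(mapResidues(msa, "x", "zz"), "not present")
})

test_that("FASTA round trip preserves names and sequences", {
  seqs <- c(one = "ACDEF", two = "GHIKL-MN")
  f <- tempfile(fileext = ".fasta")
  writeFastaSeqs(seqs, f)
  expect_identical(readFastaSeqs(f), seqs)
})
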