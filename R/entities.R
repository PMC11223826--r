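# Chain typing (protein / peptide / nucleic) and joining of duplex-forming
# nucleic chains into single entities.

.DNA_BACKBONE <- c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'",
                   "C3'", "O3'", "C2'", "O2'", "C1'",
                   "O5*", "C5*", "C4*", "O4*", "C3*", "O3*", "C2*", "O2*",
                   "C1*")

#' Per-chain residue summary
#'
#' One row per chain: residue counts by category, the number of
#' structurally resolved residues (those with at least one heavy atom;
#' with hydrogens dropped at parse time every stored residue qualifies),
#' and the chain's polymer class.
#'
#' @param assembly an [Assembly-class]
#' @return `data.frame(chain, nRes, nResolved, nStd, nNonstd, nNuc,
#'   polymerClass)` where `polymerClass` is "polypeptide", "nucleic" or
#'   `NA` for non-polymeric chains
#' @export
chainSummary <- function(assembly) {
  stopifnot(is(assembly, "Assembly"))
  a <- assembly@atoms
  res <- unique(a[, c("chain", "resno", "insert", "resid", "category")])
  out <- do.call(rbind, lapply(split(res, res$chain), function(r) {
    nStd <- sum(r$category == "standard-aa")
    nNonstd <- sum(r$category == "nonstandard-aa")
    nNuc <- sum(r$category == "nucleotide")
    nPep <- nStd + nNonstd
    # majority rule for hybrid chains; at least 2 linked residues required
    pc <- NA_character_
    if (nPep >= 2 || nNuc >= 2) {
      pc <- if (nPep >= nNuc) "polypeptide" else "nucleic"
      if (nPep > 0 && nNuc > 0)
        message("chain ", r$chain[1], ": mixed residue classes, ",
                "classified by majority as ", pc)
    }
    data.frame(chain = r$chain[1], nRes = nrow(r),
               nResolved = nPep + nNuc, nStd = nStd, nNonstd = nNonstd,
               nNuc = nNuc, polymerClass = pc, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chain), , drop = FALSE]
}

#' The peptide/protein decision rule
#'
#' Pure classification of a polypeptide chain from its resolved residue
#' count and non-standard residue count: fewer than 20 resolved residues is
#' a peptide; fewer than 40 is a peptide when more than half of the
#' resolved residues are non-standard amino acids; anything else is a
#' protein.  Both boundaries are strict.
#'
#' @param nResolved number of structurally resolved residues
#' @param nNonstandard how many of them are non-standard amino acids
#' @return `"peptide"` or `"protein"`
#' @export
classifyPolypeptide <- function(nResolved, nNonstandard = 0) {
  stopifnot(nNonstandard <= nResolved)
  if (nResolved < 20) return("peptide")
  if (nResolved < 40 && nNonstandard > nResolved / 2) return("peptide")
  "protein"
}

#' Classify one chain as protein, peptide or nucleic
#'
#' @param assembly an [Assembly-class]
#' @param chain chain identifier
#' @return `"protein"`, `"peptide"` or `"nucleic"`; non-polymeric chains
#'   (only ligands/waters) raise an error
#' @export
classifyChain <- function(assembly, chain) {
  cs <- chainSummary(assembly)
  row <- cs[cs$chain == chain, , drop = FALSE]
  if (!nrow(row)) stop("no such chain: ", chain, call. = FALSE)
  if (is.na(row$polymerClass))
    stop("chain ", chain, " is not polymeric and cannot be classified",
         call. = FALSE)
  if (row$polymerClass == "nucleic") return("nucleic")
  classifyPolypeptide(row$nStd + row$nNonstd, row$nNonstd)
}

.chainSequence <- function(assembly, chain, polymerClass) {
  a <- assembly@atoms
  res <- unique(a[a$chain == chain, c("resno", "insert", "resid",
                                      "category")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  if (polymerClass == "polypeptide") {
    res <- res[res$category %in% c("standard-aa", "nonstandard-aa"), ,
               drop = FALSE]
    letters1 <- .aa321[res$resid]
    letters1[is.na(letters1)] <- "X"
  } else {
    res <- res[res$category == "nucleotide", , drop = FALSE]
    letters1 <- .nuc1[res$resid]
    letters1[is.na(letters1)] <- "N"
  }
  list(seq = paste(letters1, collapse = ""), residues = res)
}

.basePairTable <- function(assembly, chainA, chainB,
                           c1Range = c(9.0, 11.5), nMax = 9.5,
                           baseMax = 4.0) {
  a <- assembly@atoms
  nucRes <- function(ch) {
    r <- unique(a[a$chain == ch & a$category == "nucleotide",
                  c("resno", "insert")])
    r[order(r$resno, r$insert), , drop = FALSE]
  }
  getAtoms <- function(ch, resno, insert) {
    a[a$chain == ch & a$resno == resno & a$insert == insert, ,
      drop = FALSE]
  }
  keyAtom <- function(at, names) {
    hit <- at[at$elety %in% names, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    as.numeric(hit[1, c("x", "y", "z")])
  }
  resA <- nucRes(chainA)
  resB <- nucRes(chainB)
  if (!nrow(resA) || !nrow(resB)) return(NULL)
  pairs <- NULL
  for (i in seq_len(nrow(resA))) {
    atI <- getAtoms(chainA, resA$resno[i], resA$insert[i])
    c1I <- keyAtom(atI, c("C1'", "C1*"))
    nI <- keyAtom(atI, c("N9", "N1"))
    baseI <- atI[!(atI$elety %in% .DNA_BACKBONE), c("x", "y", "z"),
                 drop = FALSE]
    if (is.null(c1I) || is.null(nI) || !nrow(baseI)) next
    for (j in seq_len(nrow(resB))) {
      atJ <- getAtoms(chainB, resB$resno[j], resB$insert[j])
      c1J <- keyAtom(atJ, c("C1'", "C1*"))
      nJ <- keyAtom(atJ, c("N9", "N1"))
      baseJ <- atJ[!(atJ$elety %in% .DNA_BACKBONE), c("x", "y", "z"),
                   drop = FALSE]
      if (is.null(c1J) || is.null(nJ) || !nrow(baseJ)) next
      dC1 <- sqrt(sum((c1I - c1J)^2))
      if (dC1 < c1Range[1] || dC1 > c1Range[2]) next
      if (sqrt(sum((nI - nJ)^2)) > nMax) next
      dmin <- min(sqrt(outer(rowSums(as.matrix(baseI)^2),
                             rowSums(as.matrix(baseJ)^2), "+") -
                       2 * as.matrix(baseI) %*% t(as.matrix(baseJ))))
      if (dmin > baseMax) next
      pairs <- rbind(pairs, data.frame(i = i, j = j))
    }
  }
  pairs
}

#' Detect a Watson-Crick-like duplex between two nucleic chains
#'
#' A geometric stand-in for a full base-pairing analysis: residues i (chain
#' A) and j (chain B) are paired when their C1'-C1' distance lies in
#' [9.0, 11.5] Angstrom, their glycosidic nitrogens (N1/N9) are within 9.5
#' Angstrom and their nearest base atoms within 4.0 Angstrom.  The chains
#' form a duplex when at least `minRun` consecutive antiparallel pairs
#' exist, i.e. a run (i, j), (i+1, j-1), ...
#'
#' @param assembly an [Assembly-class]
#' @param chainA,chainB chain identifiers
#' @param minRun minimum number of consecutive pairs (default 4)
#' @return `TRUE` if the two chains form a duplex
#' @export
chainsFormDuplex <- function(assembly, chainA, chainB, minRun = 4) {
  pairs <- .basePairTable(assembly, chainA, chainB)
  if (is.null(pairs) || nrow(pairs) < minRun) return(FALSE)
  # longest antiparallel run: (i, j) followed by (i+1, j-1)
  key <- paste(pairs$i, pairs$j)
  best <- 1L
  for (k in seq_len(nrow(pairs))) {
    len <- 1L
    i <- pairs$i[k]; j <- pairs$j[k]
    while (paste(i + len, j - len) %in% key) len <- len + 1L
    best <- max(best, len)
  }
  best >= minRun
}

#' Build the entity table of an assembly
#'
#' Types every polymeric chain (protein / peptide / nucleic) and joins
#' duplex-forming nucleic chains into single nucleic entities (transitively
#' through shared chains).  Every polymeric chain ends up in exactly one
#' entity; protein and peptide entities always have one chain.
#'
#' @param assembly an [Assembly-class]
#' @param minRun minimum consecutive base pairs for a duplex join
#' @return `data.frame(entityId, kind, chains, nChains, sequence)` where
#'   `chains` is a comma-joined chain list and `sequence` the one-letter
#'   sequence (per-chain sequences joined by `,` for multi-chain entities)
#' @seealso [entityResidues()] for the residue-to-position map
#' @export
buildEntities <- function(assembly, minRun = 4) {
  cs <- chainSummary(assembly)
  cs <- cs[!is.na(cs$polymerClass), , drop = FALSE]
  if (!nrow(cs)) return(data.frame(entityId = character(0),
                                   kind = character(0),
                                   chains = character(0),
                                   nChains = integer(0),
                                   sequence = character(0)))
  kinds <- vapply(cs$chain, function(ch) classifyChain(assembly, ch), "")
  nuc <- cs$chain[kinds == "nucleic"]

  # union-find over nucleic chains joined by duplex detection
  parent <- stats::setNames(nuc, nuc)
  findRoot <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (length(nuc) > 1) {
    for (i in seq_len(length(nuc) - 1)) {
      for (j in (i + 1):length(nuc)) {
        if (chainsFormDuplex(assembly, nuc[i], nuc[j], minRun = minRun)) {
          parent[[findRoot(nuc[j])]] <- findRoot(nuc[i])
        }
      }
    }
  }

  groups <- list()
  for (ch in cs$chain) {
    if (kinds[[ch]] == "nucleic") {
      root <- findRoot(ch)
      groups[[root]] <- c(groups[[root]], ch)
    } else {
      groups[[ch]] <- ch
    }
  }
  ord <- order(vapply(groups, function(g) min(g), ""))
  groups <- groups[ord]

  rows <- lapply(seq_along(groups), function(k) {
    chs <- sort(groups[[k]])
    kind <- kinds[[chs[1]]]
    pclass <- cs$polymerClass[cs$chain == chs[1]]
    seqs <- vapply(chs, function(ch)
      .chainSequence(assembly, ch, pclass)$seq, "")
    data.frame(entityId = sprintf("E%d", k), kind = kind,
               chains = paste(chs, collapse = ","),
               nChains = length(chs),
               sequence = paste(seqs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Residue-to-sequence-position map for all entities
#'
#' @param assembly an [Assembly-class]
#' @param entities the table from [buildEntities()]
#' @return `data.frame(entityId, chain, resno, insert, resid, pos)`; `pos`
#'   is the 1-based position within the entity sequence (chains of a joined
#'   nucleic entity are concatenated in chain order)
#' @export
entityResidues <- function(assembly, entities) {
  rows <- lapply(seq_len(nrow(entities)), function(k) {
    chs <- strsplit(entities$chains[k], ",", fixed = TRUE)[[1]]
    pclass <- if (entities$kind[k] == "nucleic") "nucleic"
              else "polypeptide"
    tabs <- lapply(chs, function(ch) {
      r <- .chainSequence(assembly, ch, pclass)$residues
      if (!nrow(r)) return(NULL)
      data.frame(entityId = entities$entityId[k], chain = ch,
                 resno = r$resno, insert = r$insert, resid = r$resid,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    tab$pos <- seq_len(nrow(tab))
    tab
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
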