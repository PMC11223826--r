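# Typed binary interfaces and binding sites from residue contact maps,
# the area and uniqueness filters, and geometric bond annotation.

.itypeOf <- function(kindA, kindB) {
  ks <- sort(c(kindA, kindB))
  if (identical(ks, c("protein", "protein"))) return("PP")
  if (identical(ks, c("peptide", "protein"))) return("PPep")
  if (identical(ks, c("nucleic", "protein"))) return("PNA")
  NA_character_  # peptide-peptide, peptide-nucleic, nucleic-nucleic: not emitted
}

#' Extract typed interfaces from a residue contact map
#'
#' One interface per unordered entity pair with inter-entity contacts.
#' Interfaces with total area not strictly above `minArea` (default 100
#' Angstrom^2) are dropped, as are interaction types other than
#' protein-protein, protein-peptide and protein-nucleic acid.  Within the
#' entry, near-identical duplicates — interfaces between sequence-identical
#' entity pairs whose contact similarity is at least `dedupSimilarity` —
#' are collapsed to the largest-area representative (ties broken by
#' lexicographic chain ids).
#'
#' @param assembly an [Assembly-class]
#' @param entities the table from [buildEntities()]
#' @param rcmap a [ResidueContactMap-class]
#' @param minArea interface area threshold in Angstrom^2 (strict `>`)
#' @param dedupSimilarity contact-similarity level treated as duplicate
#' @return list of [Interface-class] objects, ordered by id
#' @export
extractInterfaces <- function(assembly, entities, rcmap, minArea = 100,
                              dedupSimilarity = 0.95) {
  stopifnot(is(assembly, "Assembly"), is(rcmap, "ResidueContactMap"))
  eres <- entityResidues(assembly, entities)
  rkey <- function(ch, no, ins) paste(ch, no, ins, sep = "\r")
  eres$key <- rkey(eres$chain, eres$resno, eres$insert)
  ct <- rcmap@contacts
  if (!nrow(ct)) return(list())
  keyA <- rkey(ct$chain_a, ct$resno_a, ct$insert_a)
  keyB <- rkey(ct$chain_b, ct$resno_b, ct$insert_b)
  ia <- match(keyA, eres$key)
  ib <- match(keyB, eres$key)
  ok <- !is.na(ia) & !is.na(ib) & eres$entityId[ia] != eres$entityId[ib]
  ct <- ct[ok, , drop = FALSE]
  ia <- ia[ok]; ib <- ib[ok]
  if (!nrow(ct)) return(list())

  eA <- eres$entityId[ia]
  eB <- eres$entityId[ib]
  swap <- eA > eB
  pairKey <- ifelse(swap, paste(eB, eA), paste(eA, eB))

  kinds <- stats::setNames(entities$kind, entities$entityId)
  chainsOf <- stats::setNames(entities$chains, entities$entityId)
  seqOf <- stats::setNames(entities$sequence, entities$entityId)

  faces <- list()
  for (pk in sort(unique(pairKey))) {
    sel <- which(pairKey == pk)
    ents <- strsplit(pk, " ", fixed = TRUE)[[1]]
    # orient contacts so side a is the first entity of the pair
    sub <- ct[sel, , drop = FALSE]
    sw <- swap[sel]
    posA <- ifelse(sw, eres$pos[ib[sel]], eres$pos[ia[sel]])
    posB <- ifelse(sw, eres$pos[ia[sel]], eres$pos[ib[sel]])
    getside <- function(cols, swapped) {
      out <- sub[, cols, drop = FALSE]
      alt <- sub[, sub("_a$", "_b", cols), drop = FALSE]
      for (cc in seq_along(cols))
        out[swapped, cc] <- alt[swapped, cc]
      out
    }
    aCols <- c("chain_a", "resno_a", "insert_a", "resid_a", "category_a")
    bCols <- c("chain_b", "resno_b", "insert_b", "resid_b", "category_b")
    sideA <- getside(aCols, sw)
    bAlt <- sub[, aCols, drop = FALSE]
    sideB <- sub[, bCols, drop = FALSE]
    for (cc in seq_along(bCols)) sideB[sw, cc] <- bAlt[sw, cc]
    contacts <- data.frame(sideA, sideB, pos_a = posA, pos_b = posB,
                           area = sub$area, stringsAsFactors = FALSE)
    names(contacts)[1:10] <- c(aCols, bCols)
    ord <- order(contacts$pos_a, contacts$pos_b)
    contacts <- contacts[ord, , drop = FALSE]
    rownames(contacts) <- NULL
    total <- sum(contacts$area)
    it <- .itypeOf(kinds[[ents[1]]], kinds[[ents[2]]])
    if (is.na(it) || total <= minArea) next
    # protein side first in the reported pair for mixed types
    if (it != "PP" && kinds[[ents[1]]] != "protein") {
      ents <- rev(ents)
      contacts <- contacts[, c(bCols, aCols, "pos_b", "pos_a", "area")]
      names(contacts) <- c(aCols, bCols, "pos_a", "pos_b", "area")
      contacts <- contacts[order(contacts$pos_a, contacts$pos_b), ,
                           drop = FALSE]
      rownames(contacts) <- NULL
    }
    id <- paste(assembly@entryId, assembly@assemblyId, ents[1], ents[2],
                sep = ".")
    faces[[id]] <- new("Interface", id = id, entryId = assembly@entryId,
                       assemblyId = assembly@assemblyId,
                       entityA = ents[1], entityB = ents[2],
                       kindA = kinds[[ents[1]]], kindB = kinds[[ents[2]]],
                       itype = it, contacts = contacts, totalArea = total)
  }
  if (!length(faces)) return(list())

  # uniqueness within the entry: collapse near-identical interfaces of
  # sequence-identical entity pairs
  sigOf <- vapply(faces, function(f)
    paste(sort(c(seqOf[[f@entityA]], seqOf[[f@entityB]])), collapse = "|"),
    "")
  keep <- rep(TRUE, length(faces))
  for (sig in unique(sigOf)) {
    grp <- which(sigOf == sig)
    if (length(grp) < 2) next
    # connected components under similarity >= dedupSimilarity
    n <- length(grp)
    comp <- seq_len(n)
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        s <- .dedupSimilarity(faces[[grp[u]]], faces[[grp[v]]], seqOf)
        if (s >= dedupSimilarity)
          comp[comp == comp[v]] <- comp[u]
      }
    }
    for (cid in unique(comp)) {
      members <- grp[comp == cid]
      if (length(members) < 2) next
      areas <- vapply(faces[members], totalArea, 0)
      chainlab <- vapply(faces[members], function(f)
        paste(chainsOf[[f@entityA]], chainsOf[[f@entityB]]), "")
      best <- members[order(-areas, chainlab)][1]
      keep[setdiff(members, best)] <- FALSE
    }
  }
  faces <- faces[keep]
  faces[order(names(faces))]
}

# contact similarity between two interfaces of sequence-identical entity
# pairs, using position-identity correspondences; both side-pairings when
# the pair is sequence-symmetric
.dedupSimilarity <- function(f1, f2, seqOf) {
  n1a <- nchar(gsub(",", "", seqOf[[f1@entityA]]))
  n1b <- nchar(gsub(",", "", seqOf[[f1@entityB]]))
  pairings <- list()
  if (seqOf[[f1@entityA]] == seqOf[[f2@entityA]] &&
      seqOf[[f1@entityB]] == seqOf[[f2@entityB]])
    pairings <- c(pairings, list(list(left = identityCorrespondence(n1a),
                                      right = identityCorrespondence(n1b))))
  if (seqOf[[f1@entityA]] == seqOf[[f2@entityB]] &&
      seqOf[[f1@entityB]] == seqOf[[f2@entityA]]) {
    sw <- data.frame(pos_a = f2@contacts$pos_b, pos_b = f2@contacts$pos_a,
                     area = f2@contacts$area)
    s <- interfaceContactSimilarity(
      f1@contacts, sw, list(left = identityCorrespondence(n1a),
                            right = identityCorrespondence(n1b)))
    if (!length(pairings)) return(s)
    return(max(s, interfaceContactSimilarity(f1@contacts, f2@contacts,
                                             pairings)))
  }
  if (!length(pairings)) return(0)
  interfaceContactSimilarity(f1@contacts, f2@contacts, pairings)
}

#' Derive binding sites from interfaces
#'
#' For every interface and each of its protein-kind sides, projects the
#' contacts onto that side: the binding site is the set of protein
#' residues in contact with the partner entity, each with its summed
#' contact area.  A protein engaged in n interfaces yields n binding
#' sites; grouping happens later, in clustering.
#'
#' @param interfaces list of [Interface-class]
#' @return list of [BindingSite-class]
#' @export
deriveBindingSites <- function(interfaces) {
  sites <- list()
  for (f in interfaces) {
    sideKinds <- c(f@kindA, f@kindB)
    for (side in which(sideKinds == "protein")) {
      ct <- f@contacts
      if (side == 1) {
        cols <- c("chain_a", "resno_a", "insert_a", "resid_a", "pos_a")
        ent <- f@entityA; partner <- f@entityB; pkind <- f@kindB
      } else {
        cols <- c("chain_b", "resno_b", "insert_b", "resid_b", "pos_b")
        ent <- f@entityB; partner <- f@entityA; pkind <- f@kindA
      }
      sub <- ct[, c(cols, "area")]
      names(sub) <- c("chain", "resno", "insert", "resid", "pos", "area")
      agg <- rowsum(sub$area, sub$pos)
      first <- sub[!duplicated(sub$pos), , drop = FALSE]
      first <- first[order(first$pos), , drop = FALSE]
      residues <- data.frame(first[, c("chain", "resno", "insert",
                                       "resid", "pos")],
                             area = as.numeric(agg[match(
                               first$pos, as.integer(rownames(agg)))]),
                             stringsAsFactors = FALSE)
      rownames(residues) <- NULL
      id <- paste(f@id, ent, sep = ":")
      sites[[id]] <- new("BindingSite", id = id, entryId = f@entryId,
                         entityId = ent, partnerEntity = partner,
                         partnerKind = pkind, residues = residues,
                         totalArea = sum(residues$area))
    }
  }
  sites[order(names(sites))]
}

# hydrogen-bond donor/acceptor dictionaries (heavy atoms; side chains plus
# backbone); each donor carries its antecedent for the angle criterion
.hbDonors <- list(
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  LYS = c(NZ = "CE"), HIS = c(ND1 = "CG", NE2 = "CD2"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  TRP = c(NE1 = "CD1"), CYS = c(SG = "CB"))
.hbBackboneDonor <- c(N = "CA")
.hbAcceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = "SD")
.hbBackboneAcceptor <- c("O", "OXT")
.hbNucleicAcceptor <- c("OP1", "OP2", "O5'", "O3'", "O4'", "O2'",
                        "O2", "O4", "O6", "N1", "N3", "N7")
.sbBasicN <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("ND1", "NE2"))
.sbAcidicO <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.donorTable <- function(at) {
  rows <- lapply(seq_len(nrow(at)), function(k) {
    resid <- at$resid[k]; nm <- at$elety[k]
    ant <- NA_character_
    if (nm %in% names(.hbBackboneDonor) &&
        at$category[k] %in% c("standard-aa", "nonstandard-aa"))
      ant <- .hbBackboneDonor[[nm]]
    d <- .hbDonors[[resid]]
    if (!is.null(d) && nm %in% names(d)) ant <- d[[nm]]
    if (is.na(ant)) return(NULL)
    data.frame(idx = k, antecedent = ant)
  })
  do.call(rbind, rows)
}

.isAcceptor <- function(at) {
  vapply(seq_len(nrow(at)), function(k) {
    resid <- at$resid[k]; nm <- at$elety[k]
    if (at$category[k] %in% c("standard-aa", "nonstandard-aa") &&
        nm %in% .hbBackboneAcceptor) return(TRUE)
    if (at$category[k] == "nucleotide" && nm %in% .hbNucleicAcceptor)
      return(TRUE)
    acc <- .hbAcceptors[[resid]]
    !is.null(acc) && nm %in% acc
  }, TRUE)
}

#' Annotate inter-entity bonds on an interface
#'
#' Counts, over atom pairs belonging to the interface's contact residues
#' and lying on opposite sides, hydrogen bonds (donor-acceptor distance <=
#' 3.5 Angstrom with antecedent-donor-acceptor angle >= 90 degrees; heavy
#' atoms only), salt bridges (any Arg/Lys/His side-chain N to any Asp/Glu
#' carboxylate O <= 4.0 Angstrom, counted per residue pair) and disulfides
#' (Cys SG-SG <= 2.5 Angstrom).
#'
#' @param interface an [Interface-class]
#' @param assembly the source [Assembly-class]
#' @param hbondMax,saltMax,ssMax distance cutoffs in Angstrom
#' @return the interface with `nHbonds`, `nSaltBridges`, `nDisulfides` set
#' @export
annotateBonds <- function(interface, assembly, hbondMax = 3.5,
                          saltMax = 4.0, ssMax = 2.5) {
  stopifnot(is(interface, "Interface"), is(assembly, "Assembly"))
  ct <- interface@contacts
  rkey <- function(ch, no, ins) paste(ch, no, ins, sep = "\r")
  keysA <- unique(rkey(ct$chain_a, ct$resno_a, ct$insert_a))
  keysB <- unique(rkey(ct$chain_b, ct$resno_b, ct$insert_b))
  a <- assembly@atoms
  akey <- rkey(a$chain, a$resno, a$insert)
  atA <- a[akey %in% keysA, , drop = FALSE]
  atB <- a[akey %in% keysB, , drop = FALSE]
  if (!nrow(atA) || !nrow(atB))
    return(.setBonds(interface, 0L, 0L, 0L))

  xyzA <- as.matrix(atA[, c("x", "y", "z")])
  xyzB <- as.matrix(atB[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
    2 * xyzA %*% t(xyzB)
  d <- sqrt(pmax(d2, 0))

  angleOK <- function(donAt, donSide, k, accXyz) {
    # antecedent in the same residue as the donor
    same <- donSide$chain == donAt$chain[k] &
      donSide$resno == donAt$resno[k] & donSide$insert == donAt$insert[k]
    antRow <- donSide[same & donSide$elety == donAt$antecedent[k], ,
                      drop = FALSE]
    if (!nrow(antRow)) return(TRUE)  # antecedent unresolved: accept
    v1 <- as.numeric(antRow[1, c("x", "y", "z")]) -
      as.numeric(donAt[k, c("x", "y", "z")])
    v2 <- accXyz - as.numeric(donAt[k, c("x", "y", "z")])
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    cosang <= 0  # angle >= 90 degrees
  }

  countHB <- function(donSide, accSide, dm) {
    dt <- .donorTable(donSide)
    if (is.null(dt)) return(0L)
    accMask <- .isAcceptor(accSide)
    n <- 0L
    don <- cbind(donSide[dt$idx, , drop = FALSE],
                 antecedent = dt$antecedent)
    for (k in seq_len(nrow(don))) {
      hits <- which(accMask & dm[dt$idx[k], ] <= hbondMax)
      for (h in hits) {
        if (angleOK(don, donSide, k,
                    as.numeric(accSide[h, c("x", "y", "z")])))
          n <- n + 1L
      }
    }
    n
  }
  nhb <- countHB(atA, atB, d) + countHB(atB, atA, t(d))

  sbPairs <- function(basSide, acdSide, dm) {
    out <- character(0)
    for (k in seq_len(nrow(basSide))) {
      bn <- .sbBasicN[[basSide$resid[k]]]
      if (is.null(bn) || !(basSide$elety[k] %in% bn)) next
      for (h in seq_len(nrow(acdSide))) {
        ao <- .sbAcidicO[[acdSide$resid[h]]]
        if (is.null(ao) || !(acdSide$elety[h] %in% ao)) next
        if (dm[k, h] <= saltMax)
          out <- c(out, paste(basSide$chain[k], basSide$resno[k],
                              acdSide$chain[h], acdSide$resno[h]))
      }
    }
    unique(out)
  }
  nsb <- length(sbPairs(atA, atB, d)) + length(sbPairs(atB, atA, t(d)))

  sgA <- which(atA$resid == "CYS" & atA$elety == "SG")
  sgB <- which(atB$resid == "CYS" & atB$elety == "SG")
  nss <- if (length(sgA) && length(sgB))
    sum(d[sgA, sgB, drop = FALSE] <= ssMax) else 0L

  .setBonds(interface, as.integer(nhb), as.integer(nsb), as.integer(nss))
}

.setBonds <- function(interface, nhb, nsb, nss) {
  interface@nHbonds <- nhb
  interface@nSaltBridges <- nsb
  interface@nDisulfides <- nss
  interface
}

#' Emit a PyMOL script selecting an interface's residues
#'
#' @param interface an [Interface-class]
#' @param structurePath path of the structure file the script should load
#' @param path output `.pml` path
#' @return `path`, invisibly
#' @export
writePymolScript <- function(interface, structurePath, path) {
  ct <- interface@contacts
  selA <- paste(sprintf("(chain %s and resi %d)", ct$chain_a, ct$resno_a),
                collapse = " or ")
  selB <- paste(sprintf("(chain %s and resi %d)", ct$chain_b, ct$resno_b),
                collapse = " or ")
  writeLines(c(sprintf("load %s", structurePath),
               sprintf("select side_a, %s", selA),
               sprintf("select side_b, %s", selB),
               "show sticks, side_a or side_b",
               "color marine, side_a", "color salmon, side_b"), path)
  invisible(path)
}
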