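# Tessellation contact areas: R surface over the compiled power-diagram
# engine, and aggregation of atom-atom areas to residue level.

#' Interatomic contact areas by tessellation
#'
#' Computes, for a set of atomic balls, the areas of the power-diagram
#' (Laguerre) faces between solvent-expanded balls — the geometric contact
#' between each pair of atoms — together with each atom's solvent-exposed
#' area (the part of its expanded sphere not claimed by any neighbour).
#' Face areas are evaluated exactly (half-plane clipping plus closed-form
#' polygon/circle intersection); solvent areas on a deterministic Fibonacci
#' lattice of `nSphere` points per atom.
#'
#' @param x an [Assembly-class] with radii assigned (see [assignRadii()]),
#'   or a numeric matrix of ball centers with 3 columns
#' @param radii ball radii in Angstrom (required when `x` is a matrix)
#' @param probe probe radius in Angstrom added to every ball (water, 1.4)
#' @param nSphere lattice points per atom for solvent areas
#' @param solvent compute solvent areas? (skipping them is faster)
#' @return `list(contacts, solvent)`: `contacts` is a
#'   `data.frame(i, j, area)` with `i < j` (1-based atom indices, only
#'   positive areas stored) and `solvent` a per-atom numeric vector
#' @examples
#' ## two balls r = 1.9 A at 3 A, probe 1.4 A: one disk face of
#' ## radius^2 = 3.3^2 - 1.5^2 = 8.64, area pi * 8.64 = 27.14 A^2
#' co <- rbind(c(0, 0, 0), c(3, 0, 0))
#' computeAtomContacts(co, radii = c(1.9, 1.9))$contacts
#' @export
computeAtomContacts <- function(x, radii = NULL, probe = 1.4,
                                nSphere = 2000, solvent = TRUE) {
  if (is(x, "Assembly")) {
    a <- x@atoms
    if (anyNA(a$radius))
      stop("assembly has unassigned radii; call assignRadii() first",
           call. = FALSE)
    coords <- as.matrix(a[, c("x", "y", "z")])
    radii <- a$radius
  } else {
    coords <- as.matrix(x)
    if (ncol(coords) != 3)
      stop("coordinate matrix must have 3 columns", call. = FALSE)
    if (is.null(radii) || length(radii) != nrow(coords))
      stop("radii must be given for every ball", call. = FALSE)
  }
  if (probe < 0) stop("probe radius must be non-negative", call. = FALSE)
  res <- vt_contacts(coords, as.numeric(radii), probe, as.integer(nSphere),
                     isTRUE(solvent))
  list(contacts = data.frame(i = res$i, j = res$j, area = res$area),
       solvent = res$solvent)
}

.resKeyIndex <- function(atoms) {
  # residue index in assembly order; canonical order for contact pairs
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  uk <- unique(key)
  match(key, uk)
}

#' Aggregate atom contacts to residue level
#'
#' Residue-pair contact area is the sum of the member atom-pair areas;
#' contacts within one residue are dropped.  Residue solvent area is the
#' sum of member atom solvent areas.
#'
#' @param assembly the [Assembly-class] the contacts were computed on
#' @param atomContacts result of [computeAtomContacts()]
#' @return a [ResidueContactMap-class]
#' @export
aggregateToResidues <- function(assembly, atomContacts) {
  stopifnot(is(assembly, "Assembly"))
  a <- assembly@atoms
  ridx <- .resKeyIndex(a)
  resTab <- unique(data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    category = a$category, stringsAsFactors = FALSE))
  rownames(resTab) <- NULL

  ac <- atomContacts$contacts
  ra <- ridx[ac$i]
  rb <- ridx[ac$j]
  inter <- ra != rb
  lo <- pmin(ra[inter], rb[inter])
  hi <- pmax(ra[inter], rb[inter])
  if (length(lo)) {
    pk <- paste(lo, hi, sep = "_")
    agg <- rowsum(ac$area[inter], pk)
    parts <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
    ia <- as.integer(parts[, 1])
    ib <- as.integer(parts[, 2])
    ord <- order(ia, ib)
    contacts <- data.frame(
      chain_a = resTab$chain[ia], resno_a = resTab$resno[ia],
      insert_a = resTab$insert[ia], resid_a = resTab$resid[ia],
      category_a = resTab$category[ia],
      chain_b = resTab$chain[ib], resno_b = resTab$resno[ib],
      insert_b = resTab$insert[ib], resid_b = resTab$resid[ib],
      category_b = resTab$category[ib],
      area = as.numeric(agg), stringsAsFactors = FALSE)[ord, , drop = FALSE]
    rownames(contacts) <- NULL
  } else {
    contacts <- data.frame(
      chain_a = character(0), resno_a = integer(0), insert_a = character(0),
      resid_a = character(0), category_a = character(0),
      chain_b = character(0), resno_b = integer(0), insert_b = character(0),
      resid_b = character(0), category_b = character(0),
      area = numeric(0), stringsAsFactors = FALSE)
  }

  solv <- atomContacts$solvent
  solvArea <- if (all(is.na(solv))) rep(NA_real_, nrow(resTab))
              else as.numeric(rowsum(solv, ridx)[, 1])
  solvent <- cbind(resTab, area = solvArea)

  new("ResidueContactMap", contacts = contacts, solvent = solvent)
}

#' Write a residue contact map as TSV
#'
#' @param rcmap a [ResidueContactMap-class]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeContactsTSV <- function(rcmap, path) {
  stopifnot(is(rcmap, "ResidueContactMap"))
  ct <- rcmap@contacts
  out <- data.frame(chain_a = ct$chain_a, resnum_a = ct$resno_a,
                    resname_a = ct$resid_a,
                    chain_b = ct$chain_b, resnum_b = ct$resno_b,
                    resname_b = ct$resid_b,
                    area = sprintf("%.2f", ct$area))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
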