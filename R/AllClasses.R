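#' @title Core S4 classes
#' @name IfaceTess-classes
#' @description
#' The package models a macromolecular structure as a flat per-atom table
#' wrapped in an \code{Assembly} object (chains and residues are views on
#' that table, not nested objects), residue-level tessellation results as a
#' \code{ResidueContactMap}, typed binary interactions as \code{Interface}
#' and \code{BindingSite}, and Taylor-Butina results as \code{ClusterSet}.
NULL

.atomCols <- c("chain", "resno", "insert", "resid", "category",
               "elety", "elesy", "x", "y", "z", "o", "radius", "hetero")

#' Assembly of macromolecular chains
#'
#' Holds one biological assembly: entry-level metadata plus a per-atom
#' table with author chain/residue numbering, element symbols, occupancies
#' and (after [assignRadii()]) van der Waals radii.  Hydrogens are dropped
#' at parse time and alternate locations are reduced to a single conformer,
#' so each row is one heavy atom of the model.
#'
#' @slot entryId entry identifier (PDB code or fixture id)
#' @slot assemblyId assembly identifier within the entry
#' @slot method experimental method string (e.g. "X-RAY DIFFRACTION")
#' @slot resolution resolution in Angstrom, `NA_real_` when not reported
#' @slot atoms per-atom `data.frame` with columns chain, resno, insert,
#'   resid, category, elety, elesy, x, y, z, o, radius, hetero
#' @export
setClass("Assembly",
  representation(entryId = "character", assemblyId = "character",
                 method = "character", resolution = "numeric",
                 atoms = "data.frame"),
  prototype(assemblyId = "1", method = "", resolution = NA_real_))

setValidity("Assembly", function(object) {
  if (length(object@entryId) != 1L || !nzchar(object@entryId))
    return("entryId must be a non-empty string")
  miss <- setdiff(.atomCols, names(object@atoms))
  if (length(miss))
    return(paste("atoms table lacks columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  r <- object@atoms$radius
  if (length(r) && !all(is.na(r) | r > 0))
    return("assigned radii must be positive")
  TRUE
})

#' Residue-level contact map
#'
#' Symmetric map of residue pairs to tessellation contact surface area
#' (Angstrom^2), together with per-residue solvent-exposed area.  Pairs are
#' stored once, in canonical residue order; zero-area pairs are not stored.
#'
#' @slot contacts `data.frame` with residue identity columns for both
#'   partners (`chain_a`, `resno_a`, `insert_a`, `resid_a`, `category_a`,
#'   and the `_b` counterparts) and a positive `area`
#' @slot solvent `data.frame` with one row per residue (`chain`, `resno`,
#'   `insert`, `resid`, `category`, `area`)
#' @export
setClass("ResidueContactMap",
  representation(contacts = "data.frame", solvent = "data.frame"))

setValidity("ResidueContactMap", function(object) {
  if (nrow(object@contacts) && any(object@contacts$area <= 0))
    return("stored contact areas must be positive")
  if (nrow(object@solvent) && any(object@solvent$area < -1e-9,
                                  na.rm = TRUE))
    return("solvent areas must be non-negative")
  TRUE
})

#' Typed binary interaction interface
#'
#' The set of residue-residue contacts between two entities, with total
#' contact area and (after [annotateBonds()]) counts of inter-entity
#' hydrogen bonds, salt bridges and disulfides.  Contacts carry both author
#' residue identities and entity sequence positions (`pos_a`, `pos_b`),
#' which the similarity measures operate on.
#'
#' @slot id interface identifier, unique within a run
#' @slot entryId,assemblyId provenance
#' @slot entityA,entityB entity identifiers (side A listed first)
#' @slot kindA,kindB entity kinds ("protein", "peptide", "nucleic")
#' @slot itype interaction type: "PP", "PPep" or "PNA"
#' @slot contacts per-contact `data.frame` (residue identities of both
#'   sides, `pos_a`, `pos_b`, `area`)
#' @slot totalArea sum of contact areas (Angstrom^2)
#' @slot nHbonds,nSaltBridges,nDisulfides bond counts, `NA` until annotated
#' @export
setClass("Interface",
  representation(id = "character", entryId = "character",
                 assemblyId = "character",
                 entityA = "character", entityB = "character",
                 kindA = "character", kindB = "character",
                 itype = "character", contacts = "data.frame",
                 totalArea = "numeric",
                 nHbonds = "integer", nSaltBridges = "integer",
                 nDisulfides = "integer"),
  prototype(nHbonds = NA_integer_, nSaltBridges = NA_integer_,
            nDisulfides = NA_integer_))

setValidity("Interface", function(object) {
  if (identical(object@entityA, object@entityB))
    return("an interface joins two distinct entities")
  if (!object@itype %in% c("PP", "PPep", "PNA"))
    return("itype must be one of PP, PPep, PNA")
  if (nrow(object@contacts) &&
      abs(sum(object@contacts$area) - object@totalArea) > 1e-6)
    return("totalArea must equal the sum of contact areas")
  TRUE
})

#' Protein binding site
#'
#' The protein-side residues of one interface, each with its summed contact
#' area to the partner entity.
#'
#' @slot id binding-site identifier
#' @slot entryId provenance
#' @slot entityId protein entity carrying the site
#' @slot partnerEntity,partnerKind the bound entity and its kind
#' @slot residues `data.frame` with residue identities, `pos` (sequence
#'   position in the protein entity) and positive `area`
#' @slot totalArea sum of residue areas (Angstrom^2)
#' @export
setClass("BindingSite",
  representation(id = "character", entryId = "character",
                 entityId = "character", partnerEntity = "character",
                 partnerKind = "character", residues = "data.frame",
                 totalArea = "numeric"))

setValidity("BindingSite", function(object) {
  if (nrow(object@residues) && any(object@residues$area <= 0))
    return("every binding-site residue must have positive area")
  if (nrow(object@residues) &&
      abs(sum(object@residues$area) - object@totalArea) > 1e-6)
    return("totalArea must equal the sum of residue areas")
  TRUE
})

#' Taylor-Butina clustering result
#'
#' A partition of items into centroid-led clusters plus singletons, at a
#' named stringency level.  `members` has one row per item with its cluster
#' id, centroid flag and similarity to the centroid; `singletons` lists the
#' items that had no above-threshold neighbour at all.
#'
#' @slot level stringency label ("identical", "high", "similar", or "")
#' @slot measure similarity measure the matrix was built with
#' @slot threshold neighbour threshold (comparisons are strict `>`)
#' @slot members `data.frame(item, cluster, isCentroid, simToCentroid)`
#' @slot singletons character vector of neighbourless items
#' @export
setClass("ClusterSet",
  representation(level = "character", measure = "character",
                 threshold = "numeric", members = "data.frame",
                 singletons = "character"),
  prototype(level = "", measure = "", threshold = 0.5))

setValidity("ClusterSet", function(object) {
  m <- object@members
  if (anyDuplicated(m$item))
    return("clusters must partition the items (duplicate member)")
  if (nrow(m)) {
    cent <- tapply(m$isCentroid, m$cluster, sum)
    if (any(cent != 1L))
      return("every cluster must have exactly one centroid")
  }
  TRUE
})

# ---- generics -------------------------------------------------------------

#' @rdname IfaceTess-classes
#' @param x an object of one of the package classes
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("expMethod", function(x) standardGeneric("expMethod"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("residueAreas", function(x) standardGeneric("residueAreas"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
#' @rdname IfaceTess-classes
#' @export
setGeneric("itype", function(x) standardGeneric("itype"))

#' @rdname IfaceTess-classes
setMethod("entryId", "Assembly", function(x) x@entryId)
#' @rdname IfaceTess-classes
setMethod("atoms", "Assembly", function(x) x@atoms)
#' @rdname IfaceTess-classes
setMethod("resolution", "Assembly", function(x) x@resolution)
#' @rdname IfaceTess-classes
setMethod("expMethod", "Assembly", function(x) x@method)
#' @rdname IfaceTess-classes
setMethod("contacts", "ResidueContactMap", function(x) x@contacts)
#' @rdname IfaceTess-classes
setMethod("contacts", "Interface", function(x) x@contacts)
#' @rdname IfaceTess-classes
setMethod("totalArea", "Interface", function(x) x@totalArea)
#' @rdname IfaceTess-classes
setMethod("totalArea", "BindingSite", function(x) x@totalArea)
#' @rdname IfaceTess-classes
setMethod("residueAreas", "BindingSite", function(x) x@residues)
#' @rdname IfaceTess-classes
setMethod("itype", "Interface", function(x) x@itype)
#' @rdname IfaceTess-classes
setMethod("clusters", "ClusterSet", function(x) {
  split(x@members$item, x@members$cluster)
})
#' @rdname IfaceTess-classes
setMethod("singletons", "ClusterSet", function(x) x@singletons)

# ---- show methods ---------------------------------------------------------

setMethod("show", "Assembly", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "resno", "insert")]))
  cat(sprintf(
    "Assembly %s (assembly %s): %d chains, %d residues, %d atoms\n",
    object@entryId, object@assemblyId,
    length(unique(a$chain)), nres, nrow(a)))
  cat(sprintf("  method: %s; resolution: %s A\n",
              ifelse(nzchar(object@method), object@method, "<unknown>"),
              ifelse(is.na(object@resolution), "<absent>",
                     format(object@resolution))))
})

setMethod("show", "ResidueContactMap", function(object) {
  cat(sprintf(
    "ResidueContactMap: %d residue pairs (total %.2f A^2), %d residues\n",
    nrow(object@contacts), sum(object@contacts$area), nrow(object@solvent)))
})

setMethod("show", "Interface", function(object) {
  cat(sprintf(
    "Interface %s [%s] %s--%s: %d contacts, area %.2f A^2\n",
    object@id, object@itype, object@entityA, object@entityB,
    nrow(object@contacts), object@totalArea))
  if (!is.na(object@nHbonds))
    cat(sprintf("  bonds: %d H-bonds, %d salt bridges, %d disulfides\n",
                object@nHbonds, object@nSaltBridges, object@nDisulfides))
})

setMethod("show", "BindingSite", function(object) {
  cat(sprintf(
    "BindingSite %s on %s (partner %s, %s): %d residues, area %.2f A^2\n",
    object@id, object@entityId, object@partnerEntity, object@partnerKind,
    nrow(object@residues), object@totalArea))
})

setMethod("show", "ClusterSet", function(object) {
  k <- length(unique(object@members$cluster))
  cat(sprintf(
    "ClusterSet [%s/%s, > %.2f]: %d items in %d clusters (%d singletons)\n",
    ifelse(nzchar(object@level), object@level, "unnamed"), object@measure,
    object@threshold, nrow(object@members), k, length(object@singletons)))
})
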