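# Contact-area-difference (CAD-score variant) similarity measures between
# interfaces and binding sites, given residue correspondences derived from
# MSA columns.
#
# The directional score with reference X against Y is
#   D(X -> Y) = 1 - sum_c min(|x_c - y_c|, x_c) / sum_c x_c
# over X's contacts c, where y_c is Y's area for the corresponding contact
# (0 when absent).  Contacts whose residues have no correspondence (MSA
# gaps) keep y_c = 0 and so contribute their full area as difference.  The
# returned similarity is the arithmetic mean of D(A -> B) and D(B -> A),
# which makes the measure symmetric as cluster membership requires.

#' Residue correspondence between two entities
#'
#' A partial, injective map between sequence positions of two entities,
#' typically read off the columns of a cluster MSA (see [mapResidues()]).
#'
#' @param from,to equal-length integer vectors of 1-based sequence
#'   positions; each `from[i]` corresponds to `to[i]`
#' @return `data.frame(from, to)` with the injectivity checked
#' @export
residueCorrespondence <- function(from = integer(0), to = integer(0)) {
  stopifnot(length(from) == length(to))
  if (anyDuplicated(from) || anyDuplicated(to))
    stop("a residue correspondence must be injective", call. = FALSE)
  data.frame(from = as.integer(from), to = as.integer(to))
}

#' Identity correspondence over n positions
#' @param n number of positions
#' @return a correspondence mapping every position to itself
#' @export
identityCorrespondence <- function(n) residueCorrespondence(seq_len(n),
                                                            seq_len(n))

.invertCorr <- function(corr) residueCorrespondence(corr$to, corr$from)

.mapPos <- function(pos, corr) {
  corr$to[match(pos, corr$from)]  # NA for unmatched positions
}

# D(X -> Y) on named area vectors living in a common key space; keys of x
# that are NA-named (unmatched) are treated as absent from y.
.cadDirectional <- function(xKeys, xAreas, yKeys, yAreas) {
  tot <- sum(xAreas)
  if (tot <= 0) stop("similarity undefined: empty reference contact set",
                     call. = FALSE)
  y <- yAreas[match(xKeys, yKeys)]
  y[is.na(y)] <- 0
  1 - sum(pmin(abs(xAreas - y), xAreas)) / tot
}

# contact table (pos_a, pos_b, area) mapped through per-side
# correspondences into the partner's position space; unmatched residues
# give NA keys which never match
.contactKeys <- function(ct, corrL = NULL, corrR = NULL) {
  pa <- ct$pos_a
  pb <- ct$pos_b
  if (!is.null(corrL)) pa <- .mapPos(pa, corrL)
  if (!is.null(corrR)) pb <- .mapPos(pb, corrR)
  ifelse(is.na(pa) | is.na(pb), NA_character_, paste(pa, pb, sep = "_"))
}

.contactSimOnePairing <- function(ctA, ctB, corrL, corrR) {
  dAB <- .cadDirectional(.contactKeys(ctA, corrL, corrR), ctA$area,
                         .contactKeys(ctB), ctB$area)
  dBA <- .cadDirectional(.contactKeys(ctB, .invertCorr(corrL),
                                      .invertCorr(corrR)), ctB$area,
                         .contactKeys(ctA), ctA$area)
  mean(c(dAB, dBA))
}

.asPairings <- function(corr) {
  # accept a single pairing list(left=, right=) or a list of pairings
  if (is.list(corr) && !is.null(corr$left)) list(corr) else corr
}

#' Interface contact similarity (CAD-score, contact variant)
#'
#' Compares the residue-pair contact areas of two interfaces of the same
#' type under one or more side-pairings, each a
#' `list(left = , right = )` of [residueCorrespondence()]s mapping A's
#' first/second side onto B's.  When several pairings are supplied (e.g.
#' both ways of matching a homodimer's sides) the best score is kept.
#'
#' @param A,B [Interface-class] objects, or bare contact tables with
#'   columns `pos_a`, `pos_b`, `area`
#' @param pairings a pairing or list of pairings (see above)
#' @return similarity in `[0, 1]`; 1 for identical contact sets, 0 for
#'   disjoint ones
#' @export
interfaceContactSimilarity <- function(A, B, pairings) {
  ctA <- if (is(A, "Interface")) A@contacts else A
  ctB <- if (is(B, "Interface")) B@contacts else B
  if (!nrow(ctA) || !nrow(ctB))
    stop("similarity undefined: empty contact set", call. = FALSE)
  scores <- vapply(.asPairings(pairings), function(p)
    .contactSimOnePairing(ctA, ctB, p$left, p$right), 0)
  max(scores)
}

.residueAreaSim <- function(posA, areaA, posB, areaB, corr) {
  if (!length(posA) || !length(posB))
    stop("similarity undefined: empty site", call. = FALSE)
  kA <- as.character(.mapPos(posA, corr))
  dAB <- .cadDirectional(kA, areaA, as.character(posB), areaB)
  kB <- as.character(.mapPos(posB, .invertCorr(corr)))
  dBA <- .cadDirectional(kB, areaB, as.character(posA), areaA)
  mean(c(dAB, dBA))
}

#' Binding-site residue-area similarity (CAD-score, residue variant)
#'
#' Compares the per-residue contact areas of two binding sites through a
#' residue correspondence; residues without a correspondence contribute
#' their full area as difference.
#'
#' @param A,B [BindingSite-class] objects, or data.frames with columns
#'   `pos` and `area`
#' @param corr a [residueCorrespondence()] from A's to B's positions
#' @return similarity in `[0, 1]`
#' @export
bindingSiteResidueAreaSimilarity <- function(A, B, corr) {
  rA <- if (is(A, "BindingSite")) A@residues else A
  rB <- if (is(B, "BindingSite")) B@residues else B
  .residueAreaSim(rA$pos, rA$area, rB$pos, rB$area, corr)
}

.marginalAreas <- function(ct, side) {
  pos <- if (side == 1) ct$pos_a else ct$pos_b
  agg <- rowsum(ct$area, pos)
  data.frame(pos = as.integer(rownames(agg)), area = as.numeric(agg))
}

#' Patch-area similarity (CAD-score, rearrangement-tolerant variant)
#'
#' For interfaces, residue-pair contacts are first marginalised to
#' per-residue interface areas on each side; the two sides are scored with
#' the residue-area measure and averaged, so rearrangements of residue
#' pairings across the interface that preserve each residue's total buried
#' area score 1.  For binding sites the residue-membership areas are scored
#' directly.
#'
#' @param A,B two [Interface-class] or two [BindingSite-class] objects (or
#'   equivalent bare tables)
#' @param pairings for interfaces: pairing(s) as in
#'   [interfaceContactSimilarity()]; for sites: a single
#'   [residueCorrespondence()]
#' @param mode `"interface"` or `"site"`
#' @return similarity in `[0, 1]`
#' @export
patchAreaSimilarity <- function(A, B, pairings,
                                mode = c("interface", "site")) {
  mode <- match.arg(mode)
  if (mode == "site")
    return(bindingSiteResidueAreaSimilarity(A, B, pairings))
  ctA <- if (is(A, "Interface")) A@contacts else A
  ctB <- if (is(B, "Interface")) B@contacts else B
  if (!nrow(ctA) || !nrow(ctB))
    stop("similarity undefined: empty contact set", call. = FALSE)
  scores <- vapply(.asPairings(pairings), function(p) {
    mA1 <- .marginalAreas(ctA, 1); mA2 <- .marginalAreas(ctA, 2)
    mB1 <- .marginalAreas(ctB, 1); mB2 <- .marginalAreas(ctB, 2)
    s1 <- .residueAreaSim(mA1$pos, mA1$area, mB1$pos, mB1$area, p$left)
    s2 <- .residueAreaSim(mA2$pos, mA2$area, mB2$pos, mB2$area, p$right)
    mean(c(s1, s2))
  }, 0)
  max(scores)
}
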