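# Taylor-Butina clustering of interfaces and binding sites inside sequence
# pre-groups, the three stringency levels, and incremental updates.

#' Taylor-Butina (sphere-exclusion) clustering
#'
#' Each item's neighbours are the items with similarity strictly above the
#' threshold.  Neighbour counts are computed once; the unassigned item with
#' the largest count (ties: earliest in input order) is repeatedly promoted
#' to centroid and assigned together with its unassigned neighbours.
#' Items with no neighbours at all are reported as singletons (and emitted
#' as their own size-1 clusters so cluster counts match "grouped into N
#' clusters" semantics).
#'
#' @param sim symmetric similarity matrix in `[0, 1]` with unit diagonal;
#'   rownames are the item ids
#' @param threshold neighbour threshold (strict `>`)
#' @param level,measure labels stored on the result
#' @return a [ClusterSet-class]
#' @export
taylorButina <- function(sim, threshold = 0.5, level = "",
                         measure = "similarity") {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n == 0) stop("empty similarity matrix", call. = FALSE)
  if (ncol(sim) != n || max(abs(sim - t(sim))) > 1e-8)
    stop("similarity matrix must be square and symmetric", call. = FALSE)
  if (any(sim < -1e-9 | sim > 1 + 1e-9))
    stop("similarities must lie in [0, 1]", call. = FALSE)
  if (any(abs(diag(sim) - 1) > 1e-8))
    stop("similarity matrix must have unit diagonal", call. = FALSE)
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  nb <- lapply(seq_len(n), function(i)
    setdiff(which(sim[i, ] > threshold), i))
  counts <- lengths(nb)
  assigned <- rep(FALSE, n)
  cluster <- integer(n)
  isCentroid <- logical(n)
  simToC <- numeric(n)
  cid <- 0L
  while (any(!assigned)) {
    cand <- which(!assigned)
    centroid <- cand[order(-counts[cand], cand)][1]
    cid <- cid + 1L
    members <- c(centroid, nb[[centroid]][!assigned[nb[[centroid]]]])
    assigned[members] <- TRUE
    cluster[members] <- cid
    isCentroid[centroid] <- TRUE
    simToC[members] <- sim[centroid, members]
  }
  members <- data.frame(item = ids, cluster = cluster,
                        isCentroid = isCentroid, simToCentroid = simToC,
                        stringsAsFactors = FALSE)
  new("ClusterSet", level = level, measure = measure,
      threshold = threshold, members = members,
      singletons = ids[counts == 0])
}

.levelSpec <- function(what) {
  # stringency levels: sequence pre-group identity and structural measure
  if (what == "interface")
    list(identical = list(seq = "95", measure = "contacts"),
         high = list(seq = "40", measure = "contacts"),
         similar = list(seq = "40", measure = "patch"))
  else
    list(identical = list(seq = "95", measure = "residue-areas"),
         high = list(seq = "40", measure = "residue-areas"),
         similar = list(seq = "40", measure = "site-areas"))
}

.itemPairings <- function(fA, fB, clMap, msas) {
  # valid side-pairings between two interfaces within one pre-group, with
  # MSA-derived correspondences
  corrOf <- function(ea, eb) {
    cl <- clMap[[ea]]
    mapResidues(msas[[cl]], ea, eb)
  }
  pairings <- list()
  if (identical(clMap[[fA@entityA]], clMap[[fB@entityA]]) &&
      identical(clMap[[fA@entityB]], clMap[[fB@entityB]]))
    pairings <- c(pairings, list(list(
      left = corrOf(fA@entityA, fB@entityA),
      right = corrOf(fA@entityB, fB@entityB), swap = FALSE)))
  if (identical(clMap[[fA@entityA]], clMap[[fB@entityB]]) &&
      identical(clMap[[fA@entityB]], clMap[[fB@entityA]]))
    pairings <- c(pairings, list(list(
      left = corrOf(fA@entityA, fB@entityB),
      right = corrOf(fA@entityB, fB@entityA), swap = TRUE)))
  pairings
}

.swapContacts <- function(ct)
  data.frame(pos_a = ct$pos_b, pos_b = ct$pos_a, area = ct$area)

.interfacePairSim <- function(fA, fB, measure, clMap, msas,
                              partnerSeqs = NULL) {
  if (!identical(fA@itype, fB@itype)) return(0)
  if (fA@itype != "PP") {
    # mixed-type interfaces: protein side through the MSA, partner side by
    # exact sequence identity (peptides/nucleic entities are not
    # sequence-clustered)
    if (!identical(clMap[[fA@entityA]], clMap[[fB@entityA]])) return(0)
    sA <- partnerSeqs[[fA@entityB]]
    sB <- partnerSeqs[[fB@entityB]]
    if (is.null(sA) || is.null(sB) || sA != sB) return(0)
    cl <- clMap[[fA@entityA]]
    pairings <- list(list(
      left = mapResidues(msas[[cl]], fA@entityA, fB@entityA),
      right = identityCorrespondence(nchar(gsub(",", "", sA))),
      swap = FALSE))
  } else {
    pairings <- .itemPairings(fA, fB, clMap, msas)
  }
  scores <- vapply(pairings, function(p) {
    ctB <- if (p$swap) .swapContacts(fB@contacts) else fB@contacts
    pr <- list(left = p$left, right = p$right)
    if (measure == "contacts")
      interfaceContactSimilarity(fA@contacts, ctB, pr)
    else
      patchAreaSimilarity(fA@contacts, ctB, pr, mode = "interface")
  }, 0)
  if (!length(scores)) 0 else max(scores)
}

.sitePairSim <- function(sA, sB, clMap, msas) {
  if (!identical(clMap[[sA@entityId]], clMap[[sB@entityId]]) ||
      !identical(sA@partnerKind, sB@partnerKind))
    return(0)
  cl <- clMap[[sA@entityId]]
  corr <- mapResidues(msas[[cl]], sA@entityId, sB@entityId)
  bindingSiteResidueAreaSimilarity(sA, sB, corr)
}

#' Cluster interfaces or binding sites at the three stringency levels
#'
#' Items are first pre-grouped by sequence cluster membership — two
#' interfaces are comparable only when both their proteins fall in the same
#' respective sequence clusters; binding sites when their protein does —
#' then each pre-group is split by Taylor-Butina on the structural
#' similarity.  The levels are: `identical` (95% sequence pre-groups,
#' contact / residue-area similarity > 0.5), `high` (40% pre-groups, same
#' structural measure) and `similar` (40% pre-groups, rearrangement-
#' tolerant patch-area measure).
#'
#' @param items named list of [Interface-class] or [BindingSite-class]
#' @param what `"interface"` or `"site"`
#' @param clusters95,clusters40 sequence clusterings (see
#'   [clusterSequences()]) of the relevant protein entity sequences, keyed
#'   by entity id
#' @param msas95,msas40 per-cluster MSAs, indexed by cluster number
#' @param threshold structural similarity threshold (strict `>`)
#' @param levels which levels to compute
#' @return named list of [ClusterSet-class], one per level
#' @export
clusterAtLevels <- function(items, what = c("interface", "site"),
                            clusters95, clusters40, msas95, msas40,
                            threshold = 0.5,
                            levels = c("identical", "high", "similar"),
                            partnerSeqs = NULL) {
  what <- match.arg(what)
  spec <- .levelSpec(what)[levels]
  tab95 <- seqClusterTable(clusters95)
  tab40 <- seqClusterTable(clusters40)
  out <- list()
  for (lv in names(spec)) {
    tab <- if (spec[[lv]]$seq == "95") tab95 else tab40
    msas <- if (spec[[lv]]$seq == "95") msas95 else msas40
    clMap <- stats::setNames(as.list(tab$cluster), tab$id)
    groupKey <- vapply(items, function(it) {
      if (what == "interface") {
        if (it@itype == "PP")
          paste(sort(c(clMap[[it@entityA]], clMap[[it@entityB]])),
                collapse = "_")
        else
          paste(clMap[[it@entityA]], it@itype, sep = "_")
      } else {
        paste(clMap[[it@entityId]], it@partnerKind, sep = "_")
      }
    }, "")
    membersAll <- NULL
    singles <- character(0)
    offset <- 0L
    for (g in sort(unique(groupKey))) {
      grp <- items[groupKey == g]
      n <- length(grp)
      sim <- diag(1, n)
      rownames(sim) <- colnames(sim) <- names(grp)
      if (n > 1) {
        for (u in seq_len(n - 1)) for (v in (u + 1):n) {
          s <- if (what == "interface")
            .interfacePairSim(grp[[u]], grp[[v]], spec[[lv]]$measure,
                              clMap, msas, partnerSeqs)
          else .sitePairSim(grp[[u]], grp[[v]], clMap, msas)
          sim[u, v] <- sim[v, u] <- s
        }
      }
      cs <- taylorButina(sim, threshold = threshold, level = lv,
                         measure = spec[[lv]]$measure)
      m <- cs@members
      m$cluster <- m$cluster + offset
      offset <- max(m$cluster)
      membersAll <- rbind(membersAll, m)
      singles <- c(singles, cs@singletons)
    }
    ord <- order(membersAll$item)
    out[[lv]] <- new("ClusterSet", level = lv,
                     measure = spec[[lv]]$measure, threshold = threshold,
                     members = membersAll[ord, , drop = FALSE],
                     singletons = sort(singles))
  }
  out
}

#' Incrementally update a cluster set with new items
#'
#' Each new item joins the existing cluster whose centroid it matches best
#' at strictly above the threshold (ties: the earlier cluster); unmatched
#' new items are clustered among themselves by [taylorButina()] and
#' appended.  Existing memberships never change.
#'
#' @param cs an existing [ClusterSet-class]
#' @param newIds ids of the new items
#' @param simFun `function(idA, idB)` returning the similarity between two
#'   items (new-centroid or new-new)
#' @param threshold similarity threshold; defaults to the set's own
#' @return the updated [ClusterSet-class]
#' @export
updateClusters <- function(cs, newIds, simFun, threshold = cs@threshold) {
  stopifnot(is(cs, "ClusterSet"))
  if (any(newIds %in% cs@members$item))
    stop("new items overlap existing members", call. = FALSE)
  cent <- cs@members[cs@members$isCentroid, , drop = FALSE]
  cent <- cent[order(cent$cluster), , drop = FALSE]
  members <- cs@members
  unmatched <- character(0)
  for (id in newIds) {
    sims <- vapply(cent$item, function(cc) simFun(id, cc), 0)
    ok <- which(sims > threshold)
    if (length(ok)) {
      best <- ok[order(-sims[ok], ok)][1]
      members <- rbind(members, data.frame(
        item = id, cluster = cent$cluster[best], isCentroid = FALSE,
        simToCentroid = sims[best], stringsAsFactors = FALSE))
    } else {
      unmatched <- c(unmatched, id)
    }
  }
  singles <- cs@singletons
  if (length(unmatched)) {
    n <- length(unmatched)
    sim <- diag(1, n)
    rownames(sim) <- colnames(sim) <- unmatched
    if (n > 1) for (u in seq_len(n - 1)) for (v in (u + 1):n)
      sim[u, v] <- sim[v, u] <- simFun(unmatched[u], unmatched[v])
    sub <- taylorButina(sim, threshold = threshold, level = cs@level,
                        measure = cs@measure)
    m <- sub@members
    m$cluster <- m$cluster + max(members$cluster)
    members <- rbind(members, m)
    singles <- c(singles, sub@singletons)
  }
  new("ClusterSet", level = cs@level, measure = cs@measure,
      threshold = threshold, members = members, singletons = singles)
}
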