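# End-to-end pipeline over a directory of structures: parse, filter,
# type entities, tessellate, extract and annotate interfaces and binding
# sites, cluster at three stringency levels, and write all outputs.

.structFiles <- function(input) {
  if (length(input) == 1 && dir.exists(input)) {
    fs <- list.files(input, full.names = TRUE,
                     pattern = "\\.(pdb|ent|cif|mmcif)(\\.gz)?$",
                     ignore.case = TRUE)
  } else {
    fs <- input[file.exists(input)]
  }
  sort(fs)
}

.fmtArea <- function(x) sprintf("%.2f", x)

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pre-processing and clustering pipeline
#'
#' Orchestrates, over one or more structure files: entry filtering
#' (non-NMR, resolution strictly better than `maxResolution`), chain
#' typing and duplex joining, tessellation contact areas, interface
#' extraction (area strictly above `minArea`, per-entry uniqueness),
#' binding-site derivation, bond annotation, sequence clustering of
#' protein entities at 95% and 40% identity with per-cluster MSAs, and
#' Taylor-Butina clustering of interfaces and binding sites at the chosen
#' stringency levels.  All tables are written with stable column order and
#' 2-decimal areas, so a rerun on the same inputs is byte-identical.
#'
#' @param input a directory or a vector of structure file paths
#' @param outDir output directory (created if needed)
#' @param probe probe radius in Angstrom
#' @param minArea interface area threshold in Angstrom^2 (strict `>`)
#' @param maxResolution entry resolution cutoff in Angstrom (strict `<`)
#' @param acceptMissingResolution keep non-NMR entries lacking resolution?
#' @param levels stringency levels to emit
#' @param writeContacts also write the residue contact TSV?
#' @param nSphere lattice points per atom for solvent areas
#' @param simThreshold structural similarity threshold for clustering
#' @param updateFrom path to a `clusters.json` manifest from an earlier
#'   run over a subset of the same inputs: memberships of previously
#'   clustered items are kept fixed and only new items are assigned
#'   (incrementally, against the stored centroids; see [updateClusters()])
#' @return invisibly, a list with the in-memory results
#'   (`entities`, `interfaces`, `sites`, `interfaceClusters`,
#'   `siteClusters`, `outDir`, `log`)
#' @export
runPipeline <- function(input, outDir, probe = 1.4, minArea = 100,
                        maxResolution = 4.0,
                        acceptMissingResolution = FALSE,
                        levels = c("identical", "high", "similar"),
                        writeContacts = TRUE, nSphere = 2000,
                        simThreshold = 0.5, updateFrom = NULL) {
  files <- .structFiles(input)
  if (!length(files))
    stop("no structure files found in input", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  say("inputs: %d structure file(s)", length(files))

  allEnt <- NULL
  allIfaces <- list()
  allSites <- list()
  contactTabs <- list()
  nParsed <- 0L
  for (f in files) {
    asm <- tryCatch(parseStructure(f), error = function(e) {
      say("skip %s: %s", basename(f), conditionMessage(e))
      NULL
    })
    if (is.null(asm)) next
    if (!entryPassesFilters(asm, maxResolution,
                            acceptMissingResolution)) {
      say("entry %s rejected by method/resolution filter", asm@entryId)
      next
    }
    nParsed <- nParsed + 1L
    asm <- suppressWarnings(assignRadii(asm))
    ents <- buildEntities(asm)
    if (!nrow(ents)) {
      say("entry %s: no polymeric entities", asm@entryId)
      next
    }
    ac <- computeAtomContacts(asm, probe = probe, nSphere = nSphere)
    rc <- aggregateToResidues(asm, ac)
    ifs <- extractInterfaces(asm, ents, rc, minArea = minArea)
    ifs <- lapply(ifs, annotateBonds, assembly = asm)
    sites <- deriveBindingSites(ifs)
    say("entry %s: %d entities, %d residue contacts, %d interfaces, %d binding sites",
        asm@entryId, nrow(ents), nrow(rc@contacts), length(ifs),
        length(sites))

    # globalize entity ids across entries
    gid <- function(e) paste(asm@entryId, e, sep = ".")
    ents$entityId <- gid(ents$entityId)
    ents <- cbind(entry = asm@entryId, ents)
    ifs <- lapply(ifs, function(x) {
      x@entityA <- gid(x@entityA); x@entityB <- gid(x@entityB); x
    })
    sites <- lapply(sites, function(x) {
      x@entityId <- gid(x@entityId)
      x@partnerEntity <- gid(x@partnerEntity); x
    })
    allEnt <- rbind(allEnt, ents)
    allIfaces <- c(allIfaces, ifs)
    allSites <- c(allSites, sites)
    if (writeContacts) {
      ct <- rc@contacts
      if (nrow(ct)) contactTabs[[asm@entryId]] <- cbind(entry = asm@entryId,
                                                        ct)
    }
  }
  if (!nParsed) stop("no entries passed filters", call. = FALSE)

  # sequence clustering of protein entities at both identity levels
  protSeqs <- stats::setNames(allEnt$sequence, allEnt$entityId)[
    allEnt$kind == "protein"]
  interfaceClusters <- siteClusters <- NULL
  if (length(protSeqs)) {
    cl95 <- clusterSequences(protSeqs, 0.95)
    cl40 <- clusterSequences(protSeqs, 0.40)
    msas95 <- lapply(cl95, buildMsa, seqs = protSeqs)
    msas40 <- lapply(cl40, buildMsa, seqs = protSeqs)
    say("sequence clusters: %d at 95%%, %d at 40%% (%d protein entities)",
        length(cl95), length(cl40), length(protSeqs))
    partnerSeqs <- stats::setNames(allEnt$sequence, allEnt$entityId)
    if (length(allIfaces))
      interfaceClusters <- clusterAtLevels(
        allIfaces, "interface", cl95, cl40, msas95, msas40,
        threshold = simThreshold, levels = levels,
        partnerSeqs = partnerSeqs)
    if (length(allSites))
      siteClusters <- clusterAtLevels(
        allSites, "site", cl95, cl40, msas95, msas40,
        threshold = simThreshold, levels = levels)

    if (!is.null(updateFrom)) {
      prev <- jsonlite::read_json(updateFrom)
      tab95l <- seqClusterTable(cl95)
      tab40l <- seqClusterTable(cl40)
      redo <- function(csNew, items, what, lv) {
        spec <- .levelSpec(what)[[lv]]
        tab <- if (spec$seq == "95") tab95l else tab40l
        msas <- if (spec$seq == "95") msas95 else msas40
        clMapL <- stats::setNames(as.list(tab$cluster), tab$id)
        simFun <- function(a, b) {
          if (what == "interface")
            .interfacePairSim(items[[a]], items[[b]], spec$measure,
                              clMapL, msas, partnerSeqs)
          else .sitePairSim(items[[a]], items[[b]], clMapL, msas)
        }
        old <- prev[[lv]][[if (what == "interface") "interfaces"
                           else "sites"]]
        if (is.null(old)) return(csNew)
        mem <- do.call(rbind, lapply(seq_along(old), function(k) {
          g <- old[[k]]
          data.frame(item = unlist(g$members), cluster = k,
                     isCentroid = unlist(g$members) == g$centroid,
                     simToCentroid = unlist(g$sim),
                     stringsAsFactors = FALSE)
        }))
        dropped <- setdiff(mem$item, names(items))
        if (length(dropped)) {
          say("update %s/%s: %d previously clustered item(s) absent from this run",
              what, lv, length(dropped))
          keepCl <- !(mem$cluster %in%
                        mem$cluster[mem$item %in% dropped & mem$isCentroid])
          mem <- mem[keepCl & !(mem$item %in% dropped), , drop = FALSE]
          mem$cluster <- match(mem$cluster, sort(unique(mem$cluster)))
        }
        oldCS <- new("ClusterSet", level = lv, measure = spec$measure,
                     threshold = simThreshold, members = mem,
                     singletons = character(0))
        updateClusters(oldCS, setdiff(names(items), mem$item), simFun)
      }
      for (lv in levels) {
        if (!is.null(interfaceClusters[[lv]]))
          interfaceClusters[[lv]] <- redo(interfaceClusters[[lv]],
                                          allIfaces, "interface", lv)
        if (!is.null(siteClusters[[lv]]))
          siteClusters[[lv]] <- redo(siteClusters[[lv]], allSites,
                                     "site", lv)
      }
      say("cluster update mode: memberships from %s preserved", updateFrom)
    }
  }

  # ---- outputs ----
  entTab <- data.frame(entry = allEnt$entry, entity = allEnt$entityId,
                       kind = allEnt$kind, chains = allEnt$chains,
                       n_chains = allEnt$nChains,
                       length = nchar(gsub(",", "", allEnt$sequence)),
                       sequence = allEnt$sequence)
  entTab <- entTab[order(entTab$entity), , drop = FALSE]
  .writeTSV(entTab, file.path(outDir, "entities.tsv"))

  ifTab <- do.call(rbind, lapply(allIfaces, function(x) data.frame(
    id = x@id, entry = x@entryId, assembly = x@assemblyId,
    entity_a = x@entityA, entity_b = x@entityB, itype = x@itype,
    total_area = .fmtArea(x@totalArea), n_contacts = nrow(x@contacts),
    n_hbonds = x@nHbonds, n_saltbridges = x@nSaltBridges,
    n_disulfides = x@nDisulfides)))
  if (is.null(ifTab))
    ifTab <- data.frame(id = character(0), entry = character(0),
                        assembly = character(0), entity_a = character(0),
                        entity_b = character(0), itype = character(0),
                        total_area = character(0), n_contacts = integer(0),
                        n_hbonds = integer(0), n_saltbridges = integer(0),
                        n_disulfides = integer(0))
  ifTab <- ifTab[order(ifTab$id), , drop = FALSE]
  .writeTSV(ifTab, file.path(outDir, "interfaces.tsv"))

  siteTab <- do.call(rbind, lapply(allSites, function(x) data.frame(
    id = x@id, entry = x@entryId, entity = x@entityId,
    partner_entity = x@partnerEntity, partner_kind = x@partnerKind,
    n_residues = nrow(x@residues), total_area = .fmtArea(x@totalArea))))
  if (is.null(siteTab))
    siteTab <- data.frame(id = character(0), entry = character(0),
                          entity = character(0),
                          partner_entity = character(0),
                          partner_kind = character(0),
                          n_residues = integer(0),
                          total_area = character(0))
  siteTab <- siteTab[order(siteTab$id), , drop = FALSE]
  .writeTSV(siteTab, file.path(outDir, "binding_sites.tsv"))

  resTab <- do.call(rbind, lapply(allSites, function(x)
    data.frame(site = x@id, chain = x@residues$chain,
               resnum = x@residues$resno, insert = x@residues$insert,
               resname = x@residues$resid,
               area = .fmtArea(x@residues$area))))
  if (!is.null(resTab)) {
    resTab <- resTab[order(resTab$site, resTab$chain, resTab$resnum), ,
                     drop = FALSE]
    .writeTSV(resTab, file.path(outDir, "binding_site_residues.tsv"))
  }

  if (writeContacts && length(contactTabs)) {
    ct <- do.call(rbind, contactTabs[order(names(contactTabs))])
    out <- data.frame(entry = ct$entry, chain_a = ct$chain_a,
                      resnum_a = ct$resno_a, resname_a = ct$resid_a,
                      chain_b = ct$chain_b, resnum_b = ct$resno_b,
                      resname_b = ct$resid_b, area = .fmtArea(ct$area))
    .writeTSV(out, file.path(outDir, "contacts.tsv"))
  }

  clusterRows <- function(cs, kindLabel, prefix) {
    m <- cs@members
    data.frame(item_kind = kindLabel, item = m$item, level = cs@level,
               cluster = paste0(prefix, m$cluster),
               centroid = ifelse(m$isCentroid, 1L, 0L),
               sim_to_centroid = sprintf("%.4f", m$simToCentroid))
  }
  for (lv in levels) {
    rows <- NULL
    if (!is.null(interfaceClusters[[lv]]))
      rows <- rbind(rows, clusterRows(interfaceClusters[[lv]],
                                      "interface", "I"))
    if (!is.null(siteClusters[[lv]]))
      rows <- rbind(rows, clusterRows(siteClusters[[lv]], "site", "S"))
    if (is.null(rows))
      rows <- data.frame(item_kind = character(0), item = character(0),
                         level = character(0), cluster = character(0),
                         centroid = integer(0),
                         sim_to_centroid = character(0))
    rows <- rows[order(rows$item_kind, rows$item), , drop = FALSE]
    .writeTSV(rows, file.path(outDir, sprintf("clusters_%s.tsv", lv)))
    if (!is.null(interfaceClusters[[lv]]))
      say("level %s: %d interface clusters, %d site clusters", lv,
          length(unique(interfaceClusters[[lv]]@members$cluster)),
          if (is.null(siteClusters[[lv]])) 0L
          else length(unique(siteClusters[[lv]]@members$cluster)))
  }

  manifest <- list(levels = levels, threshold = simThreshold)
  for (lv in levels) {
    manifest[[lv]] <- list(
      interfaces = if (!is.null(interfaceClusters[[lv]]))
        .clusterManifest(interfaceClusters[[lv]]) else NULL,
      sites = if (!is.null(siteClusters[[lv]]))
        .clusterManifest(siteClusters[[lv]]) else NULL)
  }
  jsonlite::write_json(manifest, file.path(outDir, "clusters.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  writeLines(log, file.path(outDir, "run.log"))
  invisible(list(entities = allEnt, interfaces = allIfaces,
                 sites = allSites, interfaceClusters = interfaceClusters,
                 siteClusters = siteClusters, outDir = outDir, log = log))
}

.clusterManifest <- function(cs) {
  m <- cs@members
  lapply(split(m, m$cluster), function(g) list(
    centroid = g$item[g$isCentroid],
    members = g$item,
    sim = round(g$simToCentroid, 4)))
}

#' Summarize pipeline outputs per entity
#'
#' Reads the tables written by [runPipeline()] and reports, per protein
#' entity, how many pairwise interactions of each type it participates in
#' and how many clusters they fall into at a given level.  Counts are
#' cross-checked against the interface table; a mismatch is an error.
#'
#' @param dir pipeline output directory
#' @param itypeFilter optionally restrict to one interaction type
#'   (`"PP"`, `"PPep"`, `"PNA"`)
#' @param level cluster level used for the cluster-count column
#' @return `data.frame(entity, itype, n_interactions, n_clusters)`
#' @export
summarizeRun <- function(dir, itypeFilter = NULL, level = "identical") {
  need <- c("entities.tsv", "interfaces.tsv",
            sprintf("clusters_%s.tsv", level))
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing pipeline output: ", f, call. = FALSE)
  ent <- read.delim(file.path(dir, "entities.tsv"))
  ifs <- read.delim(file.path(dir, "interfaces.tsv"))
  cl <- read.delim(file.path(dir, sprintf("clusters_%s.tsv", level)))
  cl <- cl[cl$item_kind == "interface", , drop = FALSE]

  rows <- NULL
  for (e in ent$entity[ent$kind == "protein"]) {
    sub <- ifs[ifs$entity_a == e | ifs$entity_b == e, , drop = FALSE]
    if (!is.null(itypeFilter))
      sub <- sub[sub$itype %in% itypeFilter, , drop = FALSE]
    if (!nrow(sub)) next
    for (it in sort(unique(sub$itype))) {
      ids <- sub$id[sub$itype == it]
      ncl <- length(unique(cl$cluster[cl$item %in% ids]))
      rows <- rbind(rows, data.frame(entity = e, itype = it,
                                     n_interactions = length(ids),
                                     n_clusters = ncl))
    }
  }
  if (is.null(rows))
    rows <- data.frame(entity = character(0), itype = character(0),
                       n_interactions = integer(0),
                       n_clusters = integer(0))
  # internal consistency: a PP interface is seen from both protein sides,
  # other types from their single protein side, so per-type summary totals
  # must be at least the interface-table counts
  for (it in unique(ifs$itype)) {
    if (!is.null(itypeFilter) && !(it %in% itypeFilter)) next
    got <- sum(rows$n_interactions[rows$itype == it])
    if (got < sum(ifs$itype == it))
      stop("summary inconsistent with interfaces.tsv for type ", it,
           call. = FALSE)
  }
  rows
}
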