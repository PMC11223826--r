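# Reading PDB/mmCIF files into Assembly objects, radius assignment and
# entry-level filters.  Coordinate parsing is delegated to bio3d
# (read.pdb/read.cif); header metadata is scraped separately because bio3d
# does not expose method/resolution.

#' Default van der Waals radius table
#'
#' Heavy-atom, element-keyed van der Waals radii (Angstrom) used by
#' [assignRadii()].  The values are the widely used Bondi-style set for the
#' elements common in macromolecules; any element not listed receives the
#' documented default of 1.80 Angstrom.  All tessellation results in this
#' package are defined with respect to this table.
#'
#' @return named numeric vector, element symbol to radius in Angstrom
#' @export
defaultRadiusTable <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    MG = 1.73, MN = 1.61, FE = 1.52, ZN = 1.39, CA = 1.71, `NA` = 2.27,
    K = 2.75, CU = 1.40, NI = 1.63, CO = 1.53, B = 1.92)
}

#' @rdname defaultRadiusTable
#' @format `DEFAULT_RADIUS` is the fallback radius (1.80 Angstrom) for
#'   elements absent from the table.
#' @export
DEFAULT_RADIUS <- 1.80

.elementFromName <- function(elety) {
  # derive element from an atom name when the element column is absent
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA", "CU",
              "NI", "CO")
  ifelse(two %in% known2, two, substr(nm, 1, 1))
}

.residueCategory <- function(resid, atomNames) {
  if (resid %in% .standardAA) return("standard-aa")
  if (resid %in% .nucleotides) return("nucleotide")
  if (resid %in% .waters) return("water")
  # unrecognized residues with a peptide backbone count as non-standard
  # amino acids (the peptide rule depends on this); else they are ligands
  if (all(c("N", "CA", "C") %in% atomNames)) return("nonstandard-aa")
  "ligand"
}

.scrapeHeaderPDB <- function(lines) {
  method <- ""
  resolution <- NA_real_
  ex <- grep("^EXPDTA", lines, value = TRUE)
  if (length(ex)) method <- trimws(sub("^EXPDTA\\s*", "", ex[1]))
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    v <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
    if (length(v)) resolution <- as.numeric(v)
  }
  list(method = method, resolution = resolution)
}

.scrapeHeaderCIF <- function(lines) {
  method <- ""
  resolution <- NA_real_
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  m <- grab("_exptl.method")
  if (!is.na(m)) method <- m
  for (tag in c("_refine.ls_d_res_high",
                "_em_3d_reconstruction.resolution")) {
    v <- suppressWarnings(as.numeric(grab(tag)))
    if (length(v) && !is.na(v)) { resolution <- v; break }
  }
  list(method = method, resolution = resolution)
}

.sniffFormat <- function(path) {
  base <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  stop("cannot determine structure format of '", path,
       "' (use format = \"pdb\" or \"mmcif\")", call. = FALSE)
}

#' Parse a PDB or mmCIF file into an Assembly
#'
#' Reads a macromolecular structure file (optionally gzipped) into an
#' [Assembly-class] object.  Hydrogens (and deuteriums) are discarded; for
#' alternate locations only the highest-occupancy conformer is retained,
#' ties broken by the alphabetically first altloc code; waters are retained
#' but flagged by their residue category.  Only the first model of
#' multi-model files is used.
#'
#' @param path path to a `.pdb`/`.ent`/`.cif` file, possibly `.gz`
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`
#' @param entryId entry identifier; defaults to the file base name
#' @return an [Assembly-class] (radii unassigned; see [assignRadii()])
#' @seealso [assignRadii()], [entryPassesFilters()]
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                           entryId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot parse '", path, "': file does not exist", call. = FALSE)
  gz <- grepl("\\.gz$", path)
  if (file.info(path)$size == 0)
    stop("cannot parse '", path, "': file is empty", call. = FALSE)
  if (format == "auto") format <- .sniffFormat(path)

  readPath <- path
  if (gz) {
    con <- gzfile(path, "rt")
    lines <- tryCatch(readLines(con), finally = close(con))
    readPath <- tempfile(fileext = paste0(".", format))
    writeLines(lines, readPath)
    on.exit(unlink(readPath), add = TRUE)
  }
  lines <- tryCatch(readLines(readPath, warn = FALSE),
                    error = function(e)
                      stop("cannot parse '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!length(lines) || !any(nzchar(lines)))
    stop("cannot parse '", path, "': file is empty", call. = FALSE)

  hdr <- if (format == "pdb") .scrapeHeaderPDB(lines)
         else .scrapeHeaderCIF(lines)

  pdb <- tryCatch(
    suppressWarnings(
      if (format == "pdb")
        bio3d::read.pdb(readPath, multi = FALSE, rm.alt = FALSE,
                        verbose = FALSE)
      else
        bio3d::read.cif(readPath, multi = FALSE, rm.alt = FALSE,
                        verbose = FALSE)),
    error = function(e)
      stop("cannot parse '", path, "': ", conditionMessage(e),
           call. = FALSE))

  at <- pdb$atom
  if (is.null(at) || !nrow(at))
    stop("cannot parse '", path, "': no atoms found", call. = FALSE)

  elesy <- toupper(trimws(at$elesy))
  noel <- is.na(elesy) | !nzchar(elesy)
  elesy[noel] <- .elementFromName(at$elety[noel])
  keep <- !(elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]

  occ <- at$o
  occ[is.na(occ)] <- 1
  alt <- at$alt
  alt[is.na(alt)] <- ""
  insert <- at$insert
  insert[is.na(insert)] <- ""
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- " "

  # alt-loc reduction: highest occupancy wins, ties to first altloc code
  key <- paste(chain, at$resno, insert, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  dup <- duplicated(key[ord])
  sel <- ord[!dup]
  sel <- sort(sel)

  atoms <- data.frame(
    chain = chain[sel], resno = as.integer(at$resno[sel]),
    insert = insert[sel], resid = as.character(at$resid[sel]),
    category = NA_character_, elety = as.character(at$elety[sel]),
    elesy = elesy[sel],
    x = at$x[sel], y = at$y[sel], z = at$z[sel],
    o = occ[sel], radius = NA_real_,
    hetero = at$type[sel] == "HETATM",
    stringsAsFactors = FALSE)

  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  for (k in unique(rkey)) {
    idx <- which(rkey == k)
    atoms$category[idx] <- .residueCategory(atoms$resid[idx[1]],
                                            atoms$elety[idx])
  }

  if (is.null(entryId))
    entryId <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "", basename(path),
                   ignore.case = TRUE)
  new("Assembly", entryId = entryId, assemblyId = "1",
      method = hdr$method, resolution = hdr$resolution, atoms = atoms)
}

#' Assign van der Waals radii to all atoms
#'
#' Looks every atom's element up in `table` and stores the radius on the
#' atom table.  Unknown elements receive `default` with one warning listing
#' them.  The operation is idempotent.
#'
#' @param assembly an [Assembly-class]
#' @param table named element-to-radius vector; see [defaultRadiusTable()]
#' @param default fallback radius in Angstrom for unlisted elements
#' @return the assembly with `radius` populated (all radii positive)
#' @export
assignRadii <- function(assembly, table = defaultRadiusTable(),
                        default = DEFAULT_RADIUS) {
  stopifnot(is(assembly, "Assembly"))
  el <- assembly@atoms$elesy
  r <- unname(table[el])
  unknown <- unique(el[is.na(r)])
  if (length(unknown)) {
    warning("no radius for element(s) ", paste(unknown, collapse = ", "),
            "; using default ", default, " A", call. = FALSE)
    r[is.na(r)] <- default
  }
  assembly@atoms$radius <- r
  validObject(assembly)
  assembly
}

#' Entry-level resolution/method filter
#'
#' An entry passes when its experimental method is not NMR and its reported
#' resolution is strictly better than `maxResolution` (the bound itself
#' fails).  Entries without a reported resolution are rejected by default;
#' set `acceptMissingResolution = TRUE` to keep non-NMR entries lacking the
#' annotation.
#'
#' @param assembly an [Assembly-class]
#' @param maxResolution resolution cutoff in Angstrom (strict `<`)
#' @param acceptMissingResolution keep non-NMR entries with no resolution?
#' @return `TRUE` or `FALSE`
#' @export
entryPassesFilters <- function(assembly, maxResolution = 4.0,
                               acceptMissingResolution = FALSE) {
  stopifnot(is(assembly, "Assembly"))
  if (grepl("NMR", toupper(assembly@method), fixed = TRUE)) return(FALSE)
  res <- assembly@resolution
  if (is.na(res)) {
    if (!acceptMissingResolution)
      message("entry ", assembly@entryId,
              ": no resolution annotation, rejected")
    return(acceptMissingResolution)
  }
  res < maxResolution
}

#' Write an Assembly back to PDB format
#'
#' Emits ATOM/HETATM records via bio3d plus EXPDTA and REMARK 2 header
#' lines carrying the method and resolution, so a written file re-parses to
#' the same metadata, chain ids, residue numbering and atom counts.
#'
#' @param assembly an [Assembly-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeAssemblyPDB <- function(assembly, path) {
  stopifnot(is(assembly, "Assembly"))
  a <- assembly@atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(nzchar(a$insert),
                                                   a$insert, NA),
                   o = a$o, b = rep(0, nrow(a)), elesy = a$elesy)
  body <- readLines(tmp)
  hdr <- character(0)
  if (nzchar(assembly@method))
    hdr <- c(hdr, sprintf("EXPDTA    %s", assembly@method))
  if (!is.na(assembly@resolution))
    hdr <- c(hdr, sprintf("REMARK   2 RESOLUTION. %8.2f ANGSTROMS.",
                          assembly@resolution))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an Assembly as minimal mmCIF
#'
#' Writes an `atom_site` loop (plus method/resolution tags) sufficient for
#' round-tripping fixtures through the mmCIF reader.
#'
#' @inheritParams writeAssemblyPDB
#' @return `path`, invisibly
#' @export
writeAssemblyCIF <- function(assembly, path) {
  stopifnot(is(assembly, "Assembly"))
  a <- assembly@atoms
  out <- c(sprintf("data_%s", assembly@entryId),
           "#")
  if (nzchar(assembly@method))
    out <- c(out, sprintf("_exptl.method '%s'", assembly@method))
  if (!is.na(assembly@resolution))
    out <- c(out, sprintf("_refine.ls_d_res_high %.2f",
                          assembly@resolution))
  out <- c(out, "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rec <- sprintf(
    "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
    ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)), a$elesy,
    a$elety, a$resid, a$chain, a$resno,
    ifelse(nzchar(a$insert), a$insert, "?"),
    a$x, a$y, a$z, a$o, a$resno, a$resid, a$chain, a$elety)
  writeLines(c(out, rec, "#"), path)
  invisible(path)
}
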