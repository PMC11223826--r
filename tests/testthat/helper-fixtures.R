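# In-code construction of tiny assemblies and interfaces for unit tests.

# build an Assembly from a compact atom description:
# list(list(chain, resno, resid, category, atoms = list(name = c(x,y,z))))
tinyAssembly <- function(residues, entryId = "tiny",
                         method = "X-RAY DIFFRACTION", resolution = 2.0) {
  rows <- list()
  for (r in residues) {
    for (nm in names(r$atoms)) {
      p <- r$atoms[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = r$chain, resno = as.integer(r$resno), insert = "",
        resid = r$resid, category = r$category, elety = nm,
        elesy = substr(gsub("[0-9']", "", nm), 1, 1),
        x = p[1], y = p[2], z = p[3], o = 1,
        radius = NA_real_, hetero = FALSE, stringsAsFactors = FALSE)
    }
  }
  asm <- new("Assembly", entryId = entryId, assemblyId = "1",
             method = method, resolution = resolution,
             atoms = do.call(rbind, rows))
  suppressWarnings(assignRadii(asm))
}

# an Interface built directly from a bare contact table (residue identity
# columns filled minimally; used for similarity/binding-site unit tests)
tinyInterface <- function(contactTab, itype = "PP", kinds = c("protein",
                                                              "protein")) {
  n <- nrow(contactTab)
  ct <- data.frame(
    chain_a = "A", resno_a = contactTab$pos_a, insert_a = "",
    resid_a = "ALA", category_a = "standard-aa",
    chain_b = "B", resno_b = contactTab$pos_b, insert_b = "",
    resid_b = "ALA",
    category_b = if (itype == "PNA") "nucleotide" else "standard-aa",
    pos_a = contactTab$pos_a, pos_b = contactTab$pos_b,
    area = contactTab$area, stringsAsFactors = FALSE)
  new("Interface", id = "tiny.1.E1.E2", entryId = "tiny",
      assemblyId = "1", entityA = "E1", entityB = "E2",
      kindA = kinds[1], kindB = kinds[2], itype = itype,
      contacts = ct, totalArea = sum(ct$area))
}

# a parsed+radius-assigned fixture assembly of the given kind
fixtureAssembly <- function(kind, seed = 1, ...) {
  fx <- makeAssembly(fixtureSpec(kind, seed = seed, ...))
  suppressWarnings(assignRadii(fx$assembly))
}

# residue contact map of an assembly (solvent skipped for speed)
fixtureContacts <- function(asm, probe = 1.4) {
  aggregateToResidues(asm, computeAtomContacts(asm, probe = probe,
                                               solvent = FALSE))
}
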