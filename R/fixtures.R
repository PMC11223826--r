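# Deterministic generators of idealized toy assemblies with machine-
# readable ground truth, so every pipeline stage is testable without
# external data.  Geometry uses ideal secondary-structure parameters
# (alpha-helix rise 1.5 A / twist 100 deg; B-DNA rise 3.4 A / twist 36
# deg); no claim of stereochemical realism is made.

.FIXTURE_KINDS <- c("two-ball", "helix-dimer", "homotetramer",
                    "peptide-complex", "dna-complex", "dual-mode-pair",
                    "mutant-series")

.AA1TO3 <- stats::setNames(names(.aa321), unname(.aa321))

.fixtureSeq <- function(n, seed) {
  # deterministic pseudo-random amino acid sequence
  set.seed(seed)
  paste(sample(unname(.aa321), n, replace = TRUE), collapse = "")
}

#' Fixture specification
#'
#' @param kind one of `"two-ball"`, `"helix-dimer"`, `"homotetramer"`,
#'   `"peptide-complex"`, `"dna-complex"`, `"dual-mode-pair"`,
#'   `"mutant-series"`
#' @param seed integer seed; generation is deterministic given
#'   `(spec, seed)`
#' @param ... kind-specific parameters (e.g. `nRes`, `sep`, `sequence`)
#' @return a validated spec list for [makeAssembly()]
#' @export
fixtureSpec <- function(kind, seed = 1, ...) {
  if (!kind %in% .FIXTURE_KINDS)
    stop("unknown fixture kind: ", kind, call. = FALSE)
  params <- list(...)
  if (!is.null(params$identity) &&
      any(params$identity <= 0 | params$identity > 1))
    stop("identity targets must lie in (0, 1]", call. = FALSE)
  c(list(kind = kind, seed = as.integer(seed)), params)
}

.cyl <- function(r, phiDeg, z) {
  phi <- phiDeg * pi / 180
  c(r * cos(phi), r * sin(phi), z)
}

# ideal alpha-helix backbone + CB, cylindrical offsets relative to the CA
# phase; rough but helix-like, sufficient for contact generation
.helixAtomOffsets <- list(
  N  = c(r = 1.60, dphi = -28, dz = -0.90),
  CA = c(r = 2.30, dphi = 0, dz = 0),
  C  = c(r = 1.70, dphi = 21, dz = 0.60),
  O  = c(r = 2.00, dphi = 38, dz = 1.20),
  CB = c(r = 3.30, dphi = -5, dz = 0))

.helixChain <- function(chainId, sequence, origin = c(0, 0, 0),
                        rotDeg = 0, startRes = 1) {
  aa <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(aa)) {
    phi0 <- 100 * (i - 1) + rotDeg
    z0 <- 1.5 * (i - 1)
    resid <- .AA1TO3[[aa[i]]]
    if (is.null(resid) || is.na(resid)) resid <- "UNK"
    atomNames <- names(.helixAtomOffsets)
    if (resid == "GLY") atomNames <- setdiff(atomNames, "CB")
    for (nm in atomNames) {
      off <- .helixAtomOffsets[[nm]]
      p <- .cyl(off[["r"]], phi0 + off[["dphi"]], z0 + off[["dz"]]) +
        origin
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chainId, resno = startRes + i - 1L, insert = "",
        resid = resid,
        category = if (resid %in% .standardAA) "standard-aa"
                   else "nonstandard-aa",
        elety = nm, elesy = substr(nm, 1, 1),
        x = p[1], y = p[2], z = p[3], o = 1, radius = NA_real_,
        hetero = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# one strand residue of an idealized duplex; pairIndex sets twist/rise,
# sign +1/-1 selects the strand (mirrored about the pair axis)
.dnaResidue <- function(chainId, resno, base, pairIndex, sign,
                        origin = c(0, 0, 0)) {
  theta <- 36 * (pairIndex - 1)
  z <- 3.4 * (pairIndex - 1)
  purine <- base %in% c("A", "G")
  glyc <- if (purine) "N9" else "N1"
  inner <- if (purine) "N1" else "N3"
  atoms <- list(
    c("P", 8.9, 94, 0.0), c("O5'", 8.4, 88, 0.4),
    c("C4'", 7.4, 75, 0.2), c("O3'", 8.1, 80, 1.7),
    c("C1'", 5.9, 63, 0.0), c(glyc, 4.2, 45, 0.0),
    c("C4", 2.8, 45, 0.0), c(inner, 1.6, 65, 0.0))
  rows <- lapply(atoms, function(at) {
    p <- .cyl(as.numeric(at[2]), theta + sign * as.numeric(at[3]),
              z + as.numeric(at[4])) + origin
    data.frame(chain = chainId, resno = resno, insert = "",
               resid = paste0("D", base), category = "nucleotide",
               elety = at[1], elesy = substr(gsub("[0-9']", "", at[1]),
                                             1, 1),
               x = p[1], y = p[2], z = p[3], o = 1, radius = NA_real_,
               hetero = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.complementBase <- c(A = "T", T = "A", G = "C", C = "G")

.dnaDuplex <- function(chains = c("C", "D"), sequence = "ATGCATGCATGC",
                       origin = c(0, 0, 0)) {
  bases <- strsplit(sequence, "")[[1]]
  n <- length(bases)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <-
      .dnaResidue(chains[1], i, bases[i], i, +1, origin)
    # antiparallel partner: residue j of the second strand pairs base
    # n + 1 - j, so its author numbering runs against z
    j <- n + 1L - i
    rows[[length(rows) + 1L]] <-
      .dnaResidue(chains[2], j, .complementBase[[bases[i]]], i, -1, origin)
  }
  tab <- do.call(rbind, rows)
  tab[order(tab$chain, tab$resno), , drop = FALSE]
}

.assemblyFromAtoms <- function(entryId, atoms, method = "X-RAY DIFFRACTION",
                               resolution = 2.0) {
  rownames(atoms) <- NULL
  new("Assembly", entryId = entryId, assemblyId = "1", method = method,
      resolution = resolution, atoms = atoms)
}

#' Generate a toy assembly with ground truth
#'
#' Builds the assembly described by `spec` together with a record of its
#' intended truths (chain classifications, expected entities and duplex
#' joins, expected interface types, binding mode label) that the test
#' suite verifies against actual pipeline output.
#'
#' @param spec a [fixtureSpec()]
#' @return `list(assembly = , truth = )`; for `"dual-mode-pair"` a list of
#'   two such records; for `"mutant-series"` see [makeMutantSeries()]
#' @export
makeAssembly <- function(spec) {
  kind <- spec$kind
  seed <- spec$seed
  p <- function(name, default) {
    if (!is.null(spec[[name]])) spec[[name]] else default
  }
  if (kind == "two-ball") {
    d <- p("distance", 3.0)
    atoms <- data.frame(
      chain = c("A", "B"), resno = c(1L, 1L), insert = "",
      resid = "UNK", category = "ligand", elety = "X1", elesy = "C",
      x = c(0, d), y = 0, z = 0, o = 1, radius = NA_real_, hetero = TRUE,
      stringsAsFactors = FALSE)
    return(list(assembly = .assemblyFromAtoms("twoball", atoms),
                truth = list(kind = kind, nChains = 2)))
  }
  if (kind == "helix-dimer" || kind == "homotetramer") {
    n <- p("nRes", 30)
    sep <- p("sep", 9.5)
    seqn <- p("sequence", .fixtureSeq(n, seed))
    at <- rbind(.helixChain("A", seqn),
                .helixChain("B", seqn, origin = c(sep, 0, 0),
                            rotDeg = 180))
    truth <- list(kind = kind, sequence = seqn,
                  chainClasses = list(A = "protein", B = "protein"),
                  expectedInterfaces = "PP", nEntities = 2)
    if (kind == "homotetramer") {
      at2 <- rbind(.helixChain("C", seqn, origin = c(50, 0, 0)),
                   .helixChain("D", seqn, origin = c(50 + sep, 0, 0),
                               rotDeg = 180))
      at <- rbind(at, at2)
      truth$chainClasses <- c(truth$chainClasses,
                              list(C = "protein", D = "protein"))
      truth$nEntities <- 4
      truth$uniqueInterfaces <- 1
    }
    id <- if (kind == "homotetramer") "tetramer" else "dimer"
    return(list(assembly = .assemblyFromAtoms(id, at), truth = truth))
  }
  if (kind == "peptide-complex") {
    n <- p("nRes", 30)
    npep <- p("nPep", 12)
    seqP <- p("sequence", .fixtureSeq(n, seed + 100))
    seqL <- p("pepSequence", .fixtureSeq(npep, seed + 200))
    at <- rbind(.helixChain("A", seqP),
                .helixChain("B", seqL, origin = c(9.3, 0, 8),
                            rotDeg = 180))
    return(list(assembly = .assemblyFromAtoms("pepcomplex", at),
                truth = list(kind = kind,
                             chainClasses = list(A = "protein",
                                                 B = "peptide"),
                             expectedInterfaces = "PPep", nEntities = 2)))
  }
  if (kind == "dna-complex") {
    n <- p("nRes", 30)
    seqP <- p("sequence", .fixtureSeq(n, seed + 300))
    dnaSeq <- p("dnaSequence", "ATGCATGCATGC")
    # protein helix alongside the duplex, close enough to touch it
    at <- rbind(.helixChain("A", seqP, origin = c(14.0, 0, 2)),
                .dnaDuplex(c("C", "D"), dnaSeq))
    return(list(assembly = .assemblyFromAtoms("dnacomplex", at),
                truth = list(kind = kind,
                             chainClasses = list(A = "protein",
                                                 C = "nucleic",
                                                 D = "nucleic"),
                             duplex = c("C", "D"),
                             expectedInterfaces = "PNA", nEntities = 2)))
  }
  if (kind == "dual-mode-pair") {
    n <- p("nRes", 30)
    seqA <- p("sequence", .fixtureSeq(n, seed + 400))
    seqB <- p("partnerSequence", .fixtureSeq(n, seed + 500))
    sep <- p("sep", 9.5)
    mk <- function(id, side, mode) {
      at <- rbind(.helixChain("A", seqA),
                  .helixChain("B", seqB, origin = c(side * sep, 0, 0),
                              rotDeg = 180))
      list(assembly = .assemblyFromAtoms(id, at),
           truth = list(kind = kind, mode = mode,
                        chainClasses = list(A = "protein", B = "protein"),
                        expectedInterfaces = "PP"))
    }
    return(list(mk("dualA", +1, "mode1"), mk("dualB", -1, "mode2")))
  }
  if (kind == "mutant-series") {
    base <- p("sequence", .fixtureSeq(p("nRes", 100), seed + 600))
    ids <- p("identity", c(0.95, 0.6))
    return(list(base = base,
                mutants = makeMutantSeries(base, ids, seed)))
  }
  stop("unhandled fixture kind: ", kind, call. = FALSE)
}

#' Mutant sequence series at prescribed identities
#'
#' Each output sequence differs from `base` at uniformly chosen positions
#' so that its identity to `base` is the requested fraction to within one
#' residue.
#'
#' @param base base amino acid sequence
#' @param identities identity fractions in `(0, 1]`
#' @param seed RNG seed
#' @return named character vector (names `"id0.95"` etc.)
#' @export
makeMutantSeries <- function(base, identities, seed = 1) {
  if (any(identities <= 0 | identities > 1))
    stop("identity targets must lie in (0, 1]", call. = FALSE)
  L <- nchar(base)
  set.seed(seed)
  aas <- unname(.aa321)
  out <- vapply(identities, function(f) {
    k <- round((1 - f) * L)
    if (k > L) stop("identity infeasible for length ", L, call. = FALSE)
    s <- strsplit(base, "")[[1]]
    if (k > 0) {
      posns <- sample(L, k)
      for (pp in posns) s[pp] <- sample(setdiff(aas, s[pp]), 1)
    }
    paste(s, collapse = "")
  }, "")
  stats::setNames(out, sprintf("id%g", identities))
}

#' Write a fixture to disk (PDB + ground-truth JSON sidecar)
#'
#' @param fx one `list(assembly, truth)` from [makeAssembly()]
#' @param dir output directory
#' @param format `"pdb"` or `"mmcif"`
#' @return path of the structure file, invisibly
#' @export
writeFixture <- function(fx, dir, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "pdb") ".pdb" else ".cif"
  path <- file.path(dir, paste0(fx$assembly@entryId, ext))
  if (format == "pdb") writeAssemblyPDB(fx$assembly, path)
  else writeAssemblyCIF(fx$assembly, path)
  jsonlite::write_json(fx$truth,
                       file.path(dir, paste0(fx$assembly@entryId, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write the canonical three-assembly fixture set
#'
#' A homodimer (protein-protein), a peptide complex (protein-peptide) and
#' a DNA complex (protein-nucleic), each engineered to yield exactly one
#' interface of its type; optionally also the dual-binding-mode pair.
#'
#' @param dir output directory
#' @param seed integer seed
#' @param dualMode also write the two dual-mode assemblies?
#' @return character vector of structure file paths, invisibly
#' @export
writeFixtureSet <- function(dir, seed = 1, dualMode = FALSE) {
  specs <- list(fixtureSpec("helix-dimer", seed = seed),
                fixtureSpec("peptide-complex", seed = seed),
                fixtureSpec("dna-complex", seed = seed))
  paths <- vapply(specs, function(s) writeFixture(makeAssembly(s), dir),
                  "")
  if (dualMode) {
    dm <- makeAssembly(fixtureSpec("dual-mode-pair", seed = seed))
    paths <- c(paths, vapply(dm, writeFixture, "", dir = dir))
  }
  invisible(paths)
}
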