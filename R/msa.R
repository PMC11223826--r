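# Greedy sequence clustering at an identity threshold, per-cluster MSAs
# (built-in center-star aligner, optional external MAFFT), and MSA-column
# residue correspondences.

.alignPair <- function(a, b) {
  # global alignment with fixed, documented scoring (BLOSUM62, gap 10/0.5)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  list(pattern = as.character(Biostrings::alignedPattern(al)),
       subject = as.character(Biostrings::alignedSubject(al)),
       al = al)
}

#' Pairwise sequence identity (shorter-sequence denominator)
#'
#' Identities in a global alignment divided by the length of the shorter
#' sequence — the convention of greedy incremental clustering tools.
#'
#' @param a,b character sequences (one-letter amino acid codes; `X` for
#'   non-standard residues)
#' @return identity fraction in `[0, 1]`
#' @export
seqIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  al <- .alignPair(a, b)$al
  Biostrings::pid(al, type = "PID3") / 100
}

#' Greedy incremental sequence clustering
#'
#' Sequences are sorted by length, longest first (ties by id), and each
#' joins the first existing cluster whose representative it matches at or
#' above the identity threshold, otherwise founds a new cluster.  This
#' mirrors greedy representative-based clustering as used for building the
#' sequence pre-groups at the 95% and 40% levels.
#'
#' @param seqs named character vector of sequences (names are ids)
#' @param threshold identity threshold in `[0, 1]` (e.g. 0.95 or 0.40)
#' @return list of clusters, each `list(representative, members,
#'   threshold)` with the representative first among `members`
#' @export
clusterSequences <- function(seqs, threshold) {
  if (!length(seqs)) stop("no sequences to cluster", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named", call. = FALSE)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  clusters <- list()
  for (id in names(seqs)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep <- clusters[[k]]$representative
      if (seqs[[id]] == seqs[[rep]] ||
          seqIdentity(seqs[[id]], seqs[[rep]]) >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <-
        list(representative = id, members = id, threshold = threshold)
  }
  clusters
}

#' Cluster membership lookup table
#' @param clusters result of [clusterSequences()]
#' @return `data.frame(id, cluster, representative)`
#' @export
seqClusterTable <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(k)
    data.frame(id = clusters[[k]]$members, cluster = k,
               representative = clusters[[k]]$representative,
               stringsAsFactors = FALSE)))
}

.mergeCenterStar <- function(rep, members, seqs) {
  # center-star merge of pairwise alignments to the representative
  n <- nchar(rep)
  aligns <- lapply(members, function(id) .alignPair(rep, seqs[[id]]))
  # insertions relative to representative positions 0..n
  insCount <- function(pat) {
    cnt <- integer(n + 1)
    pos <- 0L
    for (ch in strsplit(pat, "")[[1]]) {
      if (ch == "-") cnt[pos + 1L] <- cnt[pos + 1L] + 1L
      else pos <- pos + 1L
    }
    cnt
  }
  master <- integer(n + 1)
  for (al in aligns) master <- pmax(master, insCount(al$pattern))

  buildRow <- function(pat, sub) {
    p <- strsplit(pat, "")[[1]]
    s <- strsplit(sub, "")[[1]]
    out <- character(0)
    pos <- 0L
    pending <- character(0)
    flush <- function(out, pending, k)
      c(out, pending, rep("-", master[k + 1L] - length(pending)))
    for (t in seq_along(p)) {
      if (p[t] == "-") {
        pending <- c(pending, s[t])
      } else {
        out <- flush(out, pending, pos)
        pending <- character(0)
        pos <- pos + 1L
        out <- c(out, s[t])
      }
    }
    out <- flush(out, pending, pos)
    paste(out, collapse = "")
  }
  repRow <- {
    out <- character(0)
    for (k in 0:n) {
      out <- c(out, rep("-", master[k + 1L]))
      if (k < n) out <- c(out, substr(rep, k + 1, k + 1))
    }
    paste(out, collapse = "")
  }
  rows <- vapply(aligns, function(al) buildRow(al$pattern, al$subject), "")
  c(repRow, rows)
}

#' Build a multiple sequence alignment for a cluster
#'
#' Default: the built-in progressive aligner (pairwise global alignments
#' of each member to the representative, merged by the center-star
#' method), which is deterministic and dependency-free.  With
#' `aligner = "mafft"` an external MAFFT (L-INS-i) is invoked instead,
#' falling back to the built-in aligner with a warning on failure.
#'
#' @param cluster one cluster from [clusterSequences()]
#' @param seqs the named sequence vector the clustering was built from
#' @param aligner `"builtin"` or `"mafft"`
#' @return named character vector of equal-length gapped rows; degapping a
#'   row recovers the member sequence
#' @export
buildMsa <- function(cluster, seqs, aligner = c("builtin", "mafft")) {
  aligner <- match.arg(aligner)
  ids <- cluster$members
  if (!length(ids)) stop("empty cluster", call. = FALSE)
  if (length(ids) == 1L)
    return(stats::setNames(seqs[ids], ids))
  if (aligner == "mafft") {
    msa <- tryCatch(.mafftMsa(ids, seqs), error = function(e) {
      warning("external aligner failed (", conditionMessage(e),
              "); falling back to built-in aligner", call. = FALSE)
      NULL
    })
    if (!is.null(msa)) return(msa)
  }
  rep <- cluster$representative
  others <- setdiff(ids, rep)
  rows <- .mergeCenterStar(seqs[[rep]], others, seqs)
  stats::setNames(rows, c(rep, others))[ids]
}

.mafftMsa <- function(ids, seqs) {
  infile <- tempfile(fileext = ".fasta")
  outfile <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeFastaSeqs(stats::setNames(seqs[ids], ids), infile)
  status <- suppressWarnings(system2(
    "mafft", c("--localpair", "--maxiterate", "1000", "--quiet", infile),
    stdout = outfile, stderr = FALSE))
  if (!identical(status, 0L)) stop("mafft exited with status ", status)
  msa <- readFastaSeqs(outfile)
  toupper(msa[ids])
}

#' Residue correspondence from MSA columns
#'
#' Two residues correspond when they occupy the same MSA column and
#' neither row has a gap there.
#'
#' @param msa named gapped rows from [buildMsa()]
#' @param a,b member ids present in the MSA
#' @return a [residueCorrespondence()] of sequence positions (a to b)
#' @export
mapResidues <- function(msa, a, b) {
  if (!(a %in% names(msa)) || !(b %in% names(msa)))
    stop("member not present in MSA: ",
         paste(setdiff(c(a, b), names(msa)), collapse = ", "),
         call. = FALSE)
  ra <- strsplit(msa[[a]], "")[[1]]
  rb <- strsplit(msa[[b]], "")[[1]]
  if (length(ra) != length(rb))
    stop("MSA rows have unequal length", call. = FALSE)
  posA <- cumsum(ra != "-")
  posB <- cumsum(rb != "-")
  both <- ra != "-" & rb != "-"
  residueCorrespondence(posA[both], posB[both])
}

#' Read/write plain FASTA
#'
#' Thin wrappers over Biostrings for cluster sequences and MSAs.
#'
#' @param path file path
#' @return `readFastaSeqs`: named character vector
#' @export
readFastaSeqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname readFastaSeqs
#' @param seqs named character vector
#' @export
writeFastaSeqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
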