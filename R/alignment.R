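#' Nucleotide alignment container
#'
#' A light container for equal-length, named nucleotide sequences over
#' A/C/G/T, IUPAC ambiguity codes, `-` and `N`. Ambiguity codes enter the
#' likelihood as the set of compatible states; `-`, `N` and `?` are fully
#' missing.
#'
#' @param seqs named character vector of sequences, or a character matrix
#'   (taxa x sites, rownames = taxa), or an `ape::DNAbin` matrix.
#' @return object of class `mt_alignment` with fields `taxa`, `seqs`
#'   (uppercase strings) and `length`.
#' @export
as_alignment <- function(seqs) {
  if (inherits(seqs, "mt_alignment")) return(seqs)
  if (inherits(seqs, "DNAbin")) {
    m <- as.character(seqs)
    if (!is.matrix(m)) m <- do.call(rbind, m)
    seqs <- apply(m, 1, paste0, collapse = "")
  } else if (is.matrix(seqs)) {
    seqs <- apply(seqs, 1, paste0, collapse = "")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  seqs <- toupper(vapply(seqs, as.character, ""))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("all sequences must have equal length")
  if (length(seqs) < 2L) stop("alignment needs at least 2 taxa")
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), names(IUPAC_SETS))
  if (length(bad)) stop("invalid characters in alignment: ",
                        paste(bad, collapse = " "))
  structure(list(taxa = names(seqs), seqs = unname(seqs),
                 length = unname(lens[1])),
            class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("alignment:", length(x$taxa), "taxa x", x$length, "sites\n")
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"))

# 4 x 17 indicator matrix: partial likelihood column per observed symbol
iupac_partials <- local({
  m <- sapply(IUPAC_SETS, function(s) as.numeric(DNA_BASES %in% s))
  rownames(m) <- DNA_BASES
  m
})

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' @param path file path; format is sniffed from the first non-blank character
#'   (`>` means FASTA) unless given.
#' @param format one of "auto", "fasta", "phylip".
#' @return an [as_alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  d <- if (format == "fasta") {
    ape::read.FASTA(path)
  } else {
    ape::read.dna(path, format = "sequential")
  }
  as_alignment(d)
}

#' Write an alignment as FASTA (deterministic, 70-column wrap)
#'
#' @param aln an alignment coercible via [as_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  aln <- as_alignment(aln)
  con <- file(path, "wb")  # byte-stable across platforms
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    chunks <- substring(aln$seqs[i], seq(1, aln$length, 70),
                        pmin(seq(70, aln$length + 69, 70), aln$length))
    writeLines(c(paste0(">", aln$taxa[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Empirical base frequencies (missing data ignored)
#'
#' Counts unambiguous A/C/G/T across the alignment; ambiguity codes and
#' missing symbols are skipped.
#'
#' @param aln alignment.
#' @return named numeric(4) summing to 1.
#' @export
base_frequencies <- function(aln) {
  aln <- as_alignment(aln)
  ch <- unlist(strsplit(aln$seqs, ""))
  counts <- table(factor(ch, levels = DNA_BASES))
  n <- sum(counts)
  if (n == 0) stop("no unambiguous bases in alignment")
  stats::setNames(as.numeric(counts) / n, DNA_BASES)
}

# Site-pattern compression: unique columns with multiplicities, plus the
# 4 x P x ntip cube of tip partials consumed by the pruning kernel.
alignment_patterns <- function(aln) {
  aln <- as_alignment(aln)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  key <- apply(m, 2, paste0, collapse = "")
  idx <- match(key, unique(key))
  upos <- which(!duplicated(key))
  P <- length(upos)
  cube <- array(0, dim = c(4, P, length(aln$taxa)))
  for (i in seq_along(aln$taxa)) {
    cube[, , i] <- iupac_partials[, m[i, upos]]
  }
  list(cube = cube, weights = tabulate(idx, nbins = P), site_index = idx,
       taxa = aln$taxa, n_sites = aln$length)
}
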