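#' Reference genome container
#'
#' A minimal holder for a circular mtDNA reference in rCRS-style coordinates:
#' an identifier plus an upper-case nucleotide string. All variant positions in
#' the package are 1-based coordinates on this sequence (rCRS length 16,569).
#'
#' @param id character identifier.
#' @param sequence nucleotide string (alphabet A, C, G, T, N).
#' @return an object of class \code{mt_reference} with fields \code{id},
#'   \code{sequence} and \code{length}.
#' @export
reference_genome <- function(id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("reference sequence is empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("reference contains non-nucleotide characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(list(id = as.character(id), sequence = sequence,
                 length = nchar(sequence)),
            class = "mt_reference")
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return an \code{mt_reference}.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  reference_genome(names(ss)[1], as.character(ss[[1]]))
}

ref_base <- function(ref, pos) {
  stopifnot(inherits(ref, "mt_reference"))
  if (any(pos < 1L | pos > ref$length))
    stop("position out of reference range 1..", ref$length)
  substring(ref$sequence, pos, pos)
}

#' Synthetic stand-in for the rCRS
#'
#' Generates a deterministic random 16,569-base sequence usable wherever a
#' reference is needed to resolve transition/transversion kinds or codons in
#' tests and simulations. It is a synthetic surrogate, not the real rCRS; only
#' its length and coordinate conventions match.
#'
#' @param length sequence length (default 16569, the rCRS length).
#' @param seed integer seed; the default fixes the sequence package-wide.
#' @return an \code{mt_reference} with id \code{"synthetic-rCRS"}.
#' @export
synthetic_reference <- function(length = 16569L, seed = 20110110L) {
  with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                      prob = c(0.31, 0.31, 0.13, 0.25)), collapse = "")
    reference_genome("synthetic-rCRS", s)
  })
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("<mt_reference>", x$id, "-", x$length, "bp\n")
  invisible(x)
}
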