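## Functional-effect annotation of substitutions against a gene table, using
## the vertebrate mitochondrial genetic code (Biostrings table "2").

#' Read a gene annotation table
#'
#' Tab-separated file with header
#' \code{name start end type strand phase}; \code{type} is one of
#' \code{protein}, \code{tRNA}, \code{rRNA}, \code{control}; \code{phase} is
#' the 0-based offset of the first complete codon relative to \code{start}
#' (protein records only). Coordinates are closed 1-based intervals.
#'
#' @param path file path.
#' @param ref optional \code{mt_reference} used to validate coordinates.
#' @return a data frame of class \code{mt_genes}.
#' @export
read_gene_table <- function(path, ref = NULL) {
  g <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  gene_table(g, ref = ref)
}

#' @rdname read_gene_table
#' @param x data frame with the columns above.
#' @export
gene_table <- function(x, ref = NULL) {
  need <- c("name", "start", "end", "type", "strand", "phase")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("gene table misses column(s): ", paste(miss, collapse = ", "))
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$phase <- as.integer(x$phase)
  if (any(x$start > x$end)) stop("gene record with start > end")
  if (any(!x$type %in% c("protein", "tRNA", "rRNA", "control")))
    stop("unknown feature type in gene table")
  if (any(!x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(ref) && any(x$end > ref$length))
    stop("gene record beyond reference length")
  class(x) <- c("mt_genes", "data.frame")
  x
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

mito_code <- function() Biostrings::getGeneticCode("2")

#' Classify the functional effect of variants
#'
#' Substitutions in protein-coding records are translated in the record's
#' frame with the vertebrate mitochondrial genetic code and compared to the
#' reference amino acid (\code{synonymous} vs \code{nonsynonymous});
#' tRNA/rRNA/control positions return the feature type; positions covered by
#' no record return \code{intergenic}; insertions and deletions return
#' \code{indel}. The derived base of a bare transition is the reference
#' base's transition partner; heteroplasmic variants are classified by their
#' non-reference base.
#'
#' @param v an \code{mt_variants} table (or token vector).
#' @param genes an \code{mt_genes} table.
#' @param ref an \code{mt_reference}.
#' @return character vector: \code{synonymous}, \code{nonsynonymous},
#'   \code{tRNA}, \code{rRNA}, \code{control}, \code{intergenic} or
#'   \code{indel}.
#' @export
classify_functional_effect <- function(v, genes, ref) {
  v <- as_variants(v, ref = ref)
  stopifnot(inherits(genes, "mt_genes"), inherits(ref, "mt_reference"))
  code <- mito_code()
  vapply(seq_len(nrow(v)), function(i) {
    if (v$kind[i] %in% c("insertion", "deletion")) return("indel")
    pos <- v$position[i]
    hit <- which(genes$start <= pos & genes$end >= pos)
    if (!length(hit)) return("intergenic")
    rec <- genes[hit[1], ]
    if (rec$type != "protein") return(as.character(rec$type))

    rb <- ref_base(ref, pos)
    db <- v$derived[i]
    if (db == "" || v$back[i]) db <- transition_partner(rb)
    if (db == "R") db <- setdiff(c("A", "G"), rb)
    if (db == "Y") db <- setdiff(c("C", "T"), rb)

    # codon containing pos in the record's frame
    off <- pos - rec$start - rec$phase
    if (off < 0) return("intergenic")   # upstream of the first full codon
    c0 <- rec$start + rec$phase + 3L * (off %/% 3L)
    if (c0 + 2L > rec$end) stop("malformed gene record '", rec$name,
                                "': codon at ", c0, " exceeds record end")
    codon <- ref_base(ref, c0:(c0 + 2L))
    alt <- codon
    alt[pos - c0 + 1L] <- db
    codon <- paste(codon, collapse = ""); alt <- paste(alt, collapse = "")
    if (rec$strand == "-") { codon <- revcomp(codon); alt <- revcomp(alt) }
    if (identical(unname(code[codon]), unname(code[alt]))) "synonymous"
    else "nonsynonymous"
  }, character(1))
}
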