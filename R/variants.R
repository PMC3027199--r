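## rCRS-relative variant records and the position-based token nomenclature:
## bare position = transition, trailing base = transversion, "d" = deletion,
## "+S" = insertion of S after the position, "@" prefix = back mutation,
## trailing "R"/"Y" = heteroplasmic A/G or C/T state.

#' Construct a variant table
#'
#' The atom of every downstream computation: one row per rCRS-relative change.
#'
#' @param position 1-based reference positions.
#' @param kind one of \code{"transition"}, \code{"transversion"},
#'   \code{"insertion"}, \code{"deletion"} (recycled).
#' @param derived derived allele: a base for transversions, the inserted
#'   string for insertions, \code{"R"}/\code{"Y"} for heteroplasmic
#'   transitions, otherwise \code{""}.
#' @param heteroplasmic,back logical flags (recycled).
#' @return a data frame of class \code{mt_variants}.
#' @export
mt_variants <- function(position = integer(), kind = character(),
                        derived = "", heteroplasmic = FALSE, back = FALSE) {
  n <- length(position)
  v <- data.frame(position = as.integer(position),
                  kind = rep_len(as.character(kind), n),
                  derived = rep_len(as.character(derived), n),
                  heteroplasmic = rep_len(as.logical(heteroplasmic), n),
                  back = rep_len(as.logical(back), n),
                  stringsAsFactors = FALSE)
  validate_variants(v)
  class(v) <- c("mt_variants", "data.frame")
  v
}

validate_variants <- function(v) {
  ok <- v$kind %in% c("transition", "transversion", "insertion", "deletion")
  if (!all(ok)) stop("unknown variant kind: ", paste(unique(v$kind[!ok]), collapse = ", "))
  if (any(v$position < 1L)) stop("variant positions must be >= 1")
  ins <- v$kind == "insertion"
  if (any(ins & !grepl("^[ACGT]+$", v$derived)))
    stop("insertions need a non-empty derived string")
  if (any(v$kind == "deletion" & v$derived != ""))
    stop("deletions carry no derived allele")
  if (any(v$kind == "transversion" & !v$derived %in% c("A", "C", "G", "T")))
    stop("transversions need a derived base")
  invisible(v)
}

as_variants <- function(x, ref = NULL) {
  if (inherits(x, "mt_variants")) return(x)
  if (is.character(x)) return(parse_variant_token(x, ref = ref))
  stop("cannot interpret as variants: ", class(x)[1])
}

#' Parse variant tokens
#'
#' Parses tokens of the standard mtDNA nomenclature into a variant table.
#' Grammar: \code{[@]POSITION[BASE | d | +BASES | R | Y]}. A bare position is
#' a transition; a trailing base is resolved against the reference base when a
#' reference is supplied (purine/purine or pyrimidine/pyrimidine = transition,
#' otherwise transversion) and recorded as a transversion when no reference is
#' given, following the convention that suffixes annotate transversions.
#' \code{"@"} marks a back mutation; \code{"R"}/\code{"Y"} mark heteroplasmic
#' transitions.
#'
#' @param token character vector of tokens, e.g. \code{"16234"},
#'   \code{"16265C"}, \code{"249d"}, \code{"5899+C"}, \code{"@16291"}.
#' @param ref optional \code{mt_reference} used to resolve substitution kinds
#'   and validate positions.
#' @return an \code{mt_variants} table, one row per token.
#' @export
parse_variant_token <- function(token, ref = NULL) {
  token <- trimws(as.character(token))
  token <- token[nzchar(token)]
  m <- regexec("^(@?)([0-9]+)(\\+[ACGT]+|[ACGTdRY]?)$", token)
  parts <- regmatches(token, m)
  bad <- lengths(parts) == 0L
  if (any(bad)) stop("malformed variant token: ", paste(token[bad], collapse = ", "))
  back <- vapply(parts, function(p) p[2] == "@", logical(1))
  pos <- vapply(parts, function(p) as.integer(p[3]), integer(1))
  suf <- vapply(parts, function(p) p[4], character(1))
  if (!is.null(ref) && any(pos < 1L | pos > ref$length))
    stop("malformed variant token (position out of range): ",
         paste(token[pos < 1L | pos > ref$length], collapse = ", "))

  kind <- character(length(token))
  derived <- character(length(token))
  het <- logical(length(token))

  plain <- suf == ""
  kind[plain] <- "transition"; derived[plain] <- ""
  hcode <- suf %in% c("R", "Y")
  kind[hcode] <- "transition"; derived[hcode] <- suf[hcode]; het[hcode] <- TRUE
  del <- suf == "d"
  kind[del] <- "deletion"; derived[del] <- ""
  insv <- startsWith(suf, "+")
  kind[insv] <- "insertion"; derived[insv] <- sub("^\\+", "", suf[insv])
  base <- suf %in% c("A", "C", "G", "T")
  if (any(base)) {
    if (is.null(ref)) {
      kind[base] <- "transversion"
      derived[base] <- suf[base]
    } else {
      rb <- ref_base(ref, pos[base])
      same_class <- is_purine(rb) == is_purine(suf[base])
      kind[base] <- ifelse(same_class, "transition", "transversion")
      # transitions are written as bare positions: the derived base is implied
      # by the reference, so it is not stored (keeps parse/format involutive)
      derived[base] <- ifelse(same_class, "", suf[base])
    }
  }
  mt_variants(pos, kind, derived, het, back)
}

#' Format variants as tokens
#'
#' Inverse of \code{\link{parse_variant_token}}:
#' \code{parse_variant_token(format_variant(v))} reproduces \code{v}, and
#' formatting a parsed token returns its canonical form.
#'
#' @param v an \code{mt_variants} table.
#' @return character vector of tokens.
#' @export
format_variant <- function(v) {
  v <- as_variants(v)
  suf <- character(nrow(v))
  suf[v$kind == "deletion"] <- "d"
  suf[v$kind == "insertion"] <- paste0("+", v$derived[v$kind == "insertion"])
  tv <- v$kind == "transversion"
  suf[tv] <- v$derived[tv]
  hp <- v$kind == "transition" & v$heteroplasmic
  suf[hp] <- v$derived[hp]
  paste0(ifelse(v$back, "@", ""), v$position, suf)
}

#' Score an aligned sequence against the reference
#'
#' Emits one variant per difference between a gapped sample row and the
#' matching gapped reference row, in 1-based reference coordinates.
#' Substitutions are typed transition/transversion against the reference base;
#' a run of gaps in the sample emits one deletion per deleted reference base;
#' a run of gaps in the reference emits a single insertion anchored to the
#' reference position immediately 5' of the gap; IUPAC \code{R}/\code{Y} in
#' the sample matching \{reference, transition partner\} emit a heteroplasmic
#' transition. \code{N} in the sample is treated as missing data and skipped.
#'
#' @param aligned_seq sample alignment row (string, gaps as \code{"-"}).
#' @param ref an \code{mt_reference}, or the reference alignment row when the
#'   alignment contains insertions; the reference row must not start with a
#'   gap.
#' @return an \code{mt_variants} table.
#' @export
score_against_reference <- function(aligned_seq, ref) {
  ref_row <- if (inherits(ref, "mt_reference")) ref$sequence else toupper(as.character(ref))
  seq_row <- toupper(as.character(aligned_seq))
  if (nchar(seq_row) != nchar(ref_row))
    stop("aligned sequence and reference rows differ in length (",
         nchar(seq_row), " vs ", nchar(ref_row), ")")
  r <- strsplit(ref_row, "")[[1]]
  s <- strsplit(seq_row, "")[[1]]
  if (length(r) && r[1] == "-") stop("reference row must not start with a gap")
  okr <- r %in% c("A", "C", "G", "T", "N", "-")
  oks <- s %in% c("A", "C", "G", "T", "N", "R", "Y", "-")
  if (!all(okr)) stop("non-nucleotide reference character at alignment column ",
                      which(!okr)[1])
  if (!all(oks)) stop("non-nucleotide character at alignment column ", which(!oks)[1])

  pos <- integer(); kind <- character(); der <- character(); het <- logical()
  refpos <- 0L
  i <- 1L
  n <- length(r)
  while (i <= n) {
    if (r[i] == "-") {                       # insertion run, anchored 5'
      j <- i
      while (j <= n && r[j] == "-") j <- j + 1L
      bases <- s[i:(j - 1L)]
      bases <- bases[bases != "-"]
      if (length(bases)) {
        pos <- c(pos, refpos); kind <- c(kind, "insertion")
        der <- c(der, paste(bases, collapse = "")); het <- c(het, FALSE)
      }
      i <- j
      next
    }
    refpos <- refpos + 1L
    if (s[i] == "-") {
      pos <- c(pos, refpos); kind <- c(kind, "deletion"); der <- c(der, "")
      het <- c(het, FALSE)
    } else if (s[i] != r[i] && s[i] != "N" && r[i] != "N") {
      if (s[i] %in% c("R", "Y")) {
        amb <- if (s[i] == "R") c("A", "G") else c("C", "T")
        if (!r[i] %in% amb)
          stop("heteroplasmy code ", s[i], " incompatible with reference base ",
               r[i], " at position ", refpos)
        pos <- c(pos, refpos); kind <- c(kind, "transition"); der <- c(der, s[i])
        het <- c(het, TRUE)
      } else {
        same_class <- is_purine(r[i]) == is_purine(s[i])
        pos <- c(pos, refpos)
        kind <- c(kind, if (same_class) "transition" else "transversion")
        der <- c(der, if (same_class) "" else s[i])
        het <- c(het, FALSE)
      }
    }
    i <- i + 1L
  }
  mt_variants(pos, kind, der, het, FALSE)
}
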