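#' Sample variant profiles
#'
#' A profile is one sample's set of rCRS-relative variants plus its
#' population/region metadata. Variants are set-valued: duplicates by
#' (position, kind, derived allele) collapse, and equality is order-free.
#'
#' @param sample_id sample identifier.
#' @param variants an \code{mt_variants} table or character vector of tokens.
#' @param population,region free-text metadata (\code{NA} when unknown).
#' @param source \code{"study"} or \code{"literature"}.
#' @param ref optional \code{mt_reference} for token parsing.
#' @return an object of class \code{mt_profile}.
#' @export
mt_profile <- function(sample_id, variants = mt_variants(),
                       population = NA_character_, region = NA_character_,
                       source = "study", ref = NULL) {
  v <- as_variants(variants, ref = ref)
  key <- paste(v$position, v$kind, v$derived, v$back)
  v <- v[!duplicated(key), , drop = FALSE]
  v <- v[order(v$position, v$kind, v$derived), , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("mt_variants", "data.frame")
  source <- match.arg(source, c("study", "literature"))
  structure(list(sample_id = as.character(sample_id), variants = v,
                 population = as.character(population),
                 region = as.character(region), source = source),
            class = "mt_profile")
}

#' @export
print.mt_profile <- function(x, ...) {
  cat("<mt_profile>", x$sample_id,
      sprintf("[%s / %s, %s]", x$population, x$region, x$source), "\n  ",
      if (nrow(x$variants)) paste(format_variant(x$variants), collapse = " ")
      else "(no variants)", "\n")
  invisible(x)
}

profile_tokens <- function(p) format_variant(p$variants)

## positions carried by a profile, optionally restricted to a window
profile_positions <- function(p, window = NULL) {
  pos <- p$variants$position
  if (!is.null(window)) pos <- pos[pos >= window[1] & pos <= window[2]]
  sort(unique(pos))
}

#' Read and write haplotype-profile TSV files
#'
#' Tab-separated, UTF-8, header row
#' \code{sample_id population region source variants}; lines starting with
#' \code{"#"} are comments; the \code{variants} column holds space-separated
#' tokens in the standard nomenclature. \code{write_profiles} round-trips
#' through \code{read_profiles}.
#'
#' @param path file path.
#' @param ref optional \code{mt_reference} for kind resolution.
#' @return \code{read_profiles}: a list of \code{mt_profile}.
#' @export
read_profiles <- function(path, ref = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("sample_id", "population", "region", "source", "variants")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("profile TSV misses column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    toks <- strsplit(trimws(tab$variants[i]), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    mt_profile(tab$sample_id[i], toks,
               population = ifelse(nzchar(tab$population[i]), tab$population[i], NA),
               region = ifelse(nzchar(tab$region[i]), tab$region[i], NA),
               source = tab$source[i], ref = ref)
  })
}

#' @rdname read_profiles
#' @param profiles list of \code{mt_profile}.
#' @param comments character vector written as leading "#" lines.
#' @export
write_profiles <- function(profiles, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines("sample_id\tpopulation\tregion\tsource\tvariants", con)
  for (p in profiles) {
    writeLines(paste(p$sample_id,
                     ifelse(is.na(p$population), "", p$population),
                     ifelse(is.na(p$region), "", p$region),
                     p$source,
                     paste(profile_tokens(p), collapse = " "),
                     sep = "\t"), con)
  }
  invisible(path)
}
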