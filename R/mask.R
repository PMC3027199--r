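#' Site and region masks
#'
#' Holds the sites and length-variant regions disregarded in mtDNA
#' control-region analyses, plus the HVS-I clock window. The default mask
#' drops the hypermutable transition at 16519 and length variation (indels
#' only) in the C-stretches 16180-16193 and 303-315; point substitutions
#' inside those regions are retained, since only the length variation there is
#' considered unreliable. All intervals are closed and 1-based.
#'
#' @param excluded_sites positions removed outright (any variant kind).
#' @param length_regions list of \code{c(start, end)} intervals in which
#'   insertions/deletions are removed.
#' @param hvsi_window closed interval used by the HVS-I transition clock.
#' @return an object of class \code{mt_mask}.
#' @export
region_mask <- function(excluded_sites = integer(),
                        length_regions = list(),
                        hvsi_window = c(16090L, 16365L)) {
  length_regions <- lapply(length_regions, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] > iv[2]) stop("malformed interval in mask")
    iv
  })
  if (length(hvsi_window) != 2L || hvsi_window[1] > hvsi_window[2])
    stop("malformed hvsi_window")
  structure(list(excluded_sites = as.integer(excluded_sites),
                 length_regions = length_regions,
                 hvsi_window = as.integer(hvsi_window)),
            class = "mt_mask")
}

#' @rdname region_mask
#' @export
default_mask <- function() {
  region_mask(excluded_sites = 16519L,
              length_regions = list(c(16180L, 16193L), c(303L, 315L)))
}

in_intervals <- function(pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (iv in intervals) hit <- hit | (pos >= iv[1] & pos <= iv[2])
  hit
}

#' Apply a mask to variants or a profile
#'
#' Removes variants at excluded sites and indels inside the masked
#' length-variant regions. Idempotent; never adds variants.
#'
#' @param x an \code{mt_variants} table or an \code{mt_profile}.
#' @param mask an \code{mt_mask} (default \code{\link{default_mask}()}).
#' @return object of the same class as \code{x}.
#' @export
apply_mask <- function(x, mask = default_mask()) {
  if (inherits(x, "mt_profile")) {
    x$variants <- apply_mask(x$variants, mask)
    return(x)
  }
  v <- as_variants(x)
  drop <- v$position %in% mask$excluded_sites
  indel <- v$kind %in% c("insertion", "deletion")
  drop <- drop | (indel & in_intervals(v$position, mask$length_regions))
  out <- v[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mt_variants", "data.frame")
  out
}

#' Count clock-eligible HVS-I transitions
#'
#' Counts transitions inside the HVS-I clock window (16090-16365 by default)
#' after masking, excluding heteroplasmic variants and back mutations.
#' Transversions and indels never count toward a per-transition clock.
#'
#' @param x an \code{mt_variants} table or an \code{mt_profile}.
#' @param mask an \code{mt_mask} supplying the window and exclusions.
#' @param extra_excluded additional excluded positions (e.g. the pathogenic
#'   transition 11778 when dating).
#' @return a non-negative integer.
#' @export
count_hvsi_transitions <- function(x, mask = default_mask(),
                                   extra_excluded = integer()) {
  v <- if (inherits(x, "mt_profile")) x$variants else as_variants(x)
  v <- apply_mask(v, mask)
  keep <- v$kind == "transition" & !v$heteroplasmic & !v$back &
    v$position >= mask$hvsi_window[1] & v$position <= mask$hvsi_window[2] &
    !(v$position %in% as.integer(extra_excluded))
  sum(keep)
}
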