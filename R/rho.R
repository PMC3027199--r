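## The rho statistic, its heuristic standard error, and clock conversion.
##
## rho is the average mutational distance of sampled haplotypes to their most
## recent common ancestor; under a Poisson mutation model multiplying by a
## calibration rate (years per mutation) converts it to a coalescence age.
## sigma is the companion heuristic standard error
## sigma^2 = n^-2 * sum_links n_l^2 * m_l, with n_l the number of sampled
## lineages below a link and m_l the link's mutation count.

#' Construct a rooted genealogy
#'
#' A rooted mutational genealogy: links carry either an explicit mutation
#' count or a list of variant tokens (required for filtered dating), and
#' tips carry sampling multiplicities.
#'
#' @param edges data frame with columns \code{parent}, \code{child} and
#'   either \code{m} (mutation counts) or a list column \code{mutations}
#'   (token vectors, from which counts default).
#' @param root the designated ancestral node; must be the unique parentless
#'   node of \code{edges}.
#' @param multiplicity named positive integers for tips (default 1 each).
#' @return an object of class \code{mt_genealogy}.
#' @export
genealogy <- function(edges, root, multiplicity = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges)))
    stop("edges need 'parent' and 'child' columns")
  if (!"mutations" %in% names(edges)) edges$mutations <- rep(list(NULL), nrow(edges))
  if (!"m" %in% names(edges))
    edges$m <- vapply(edges$mutations, function(x) length(x %||% character()),
                      integer(1))
  edges$m <- as.integer(edges$m)
  if (any(edges$m < 0L)) stop("negative mutation count")
  if (anyDuplicated(edges$child)) stop("a node has two parents: not a tree")
  nodes <- unique(c(edges$parent, edges$child))
  parentless <- setdiff(nodes, edges$child)
  if (length(parentless) != 1L)
    stop("genealogy must have exactly one root, found: ",
         paste(parentless, collapse = ", "))
  if (!identical(as.character(root), parentless))
    stop("designated root '", root, "' is not the parentless node ('",
         parentless, "'): unrooted or misrooted input")
  tips <- setdiff(nodes, edges$parent)
  if (length(nodes) == 1L) tips <- nodes
  mult <- stats::setNames(rep(1L, length(tips)), tips)
  if (!is.null(multiplicity)) {
    if (is.null(names(multiplicity))) stop("multiplicity must be named by tip")
    unknown <- setdiff(names(multiplicity), tips)
    if (length(unknown)) stop("multiplicity for non-tip node(s): ",
                              paste(unknown, collapse = ", "))
    mult[names(multiplicity)] <- as.integer(multiplicity)
  }
  if (any(mult < 1L)) stop("tip multiplicities must be >= 1")
  structure(list(edges = edges, root = as.character(root),
                 tips = tips, multiplicity = mult),
            class = "mt_genealogy")
}

#' @export
print.mt_genealogy <- function(x, ...) {
  cat("<mt_genealogy>", length(x$tips), "tips (n =", sum(x$multiplicity),
      "), root", x$root, ",", sum(x$edges$m), "mutations\n")
  invisible(x)
}

## total tip multiplicity below each edge (below = at or under edge$child)
edge_tip_weight <- function(g) {
  children <- split(g$edges$child, g$edges$parent)
  below <- function(node) {
    if (node %in% g$tips) return(g$multiplicity[[node]])
    sum(vapply(children[[node]], below, numeric(1)))
  }
  vapply(g$edges$child, below, numeric(1))
}

#' The rho statistic
#'
#' Mean mutational path length from the sampled haplotypes to the root:
#' \eqn{\rho = n^{-1} \sum_l m_l n_l} over links, which equals the
#' multiplicity-weighted average of per-tip root path lengths.
#'
#' @param g an \code{mt_genealogy}.
#' @return a non-negative number.
#' @export
rho_statistic <- function(g) {
  stopifnot(inherits(g, "mt_genealogy"))
  n <- sum(g$multiplicity)
  if (nrow(g$edges) == 0L) return(0)
  sum(g$edges$m * edge_tip_weight(g)) / n
}

#' Heuristic standard error of rho
#'
#' Saillard-style error under a Poisson mutation model:
#' \eqn{\sigma = \sqrt{n^{-2} \sum_l n_l^2 m_l}}. Reduces to
#' \eqn{\sqrt{k/n}} on a star genealogy with k mutations per pendant branch.
#'
#' @param g an \code{mt_genealogy}.
#' @return a non-negative number.
#' @export
sigma_statistic <- function(g) {
  stopifnot(inherits(g, "mt_genealogy"))
  n <- sum(g$multiplicity)
  if (nrow(g$edges) == 0L) return(0)
  sqrt(sum(edge_tip_weight(g)^2 * g$edges$m)) / n
}

## ---- clocks ------------------------------------------------------------

#' Molecular clock specifications
#'
#' \code{hvsi_clock()} is the built-in control-region clock: 18,845 years per
#' transition in positions 16090-16365. \code{linear_clock()} builds any
#' years-per-mutation clock; \code{custom_clock()} wraps a user-supplied
#' conversion function (rho in mutations -> age in years) for calibrations
#' that are not linear in rho, e.g. whole-genome clocks with a
#' purifying-selection correction, which this package deliberately does not
#' hard-code.
#'
#' @param rate years per accepted mutation (positive).
#' @param id clock identifier.
#' @param filter which mutations the clock counts: \code{"all_accepted"},
#'   \code{"synonymous_only"} or \code{"hvsi_transitions"}.
#' @return an object of class \code{mt_clock}.
#' @export
linear_clock <- function(rate, id = paste0("linear:", rate),
                         filter = "all_accepted") {
  rate <- as.numeric(rate)
  if (!is.finite(rate) || rate <= 0) stop("clock rate must be a positive number")
  filter <- match.arg(filter, c("all_accepted", "synonymous_only",
                                "hvsi_transitions"))
  structure(list(id = id, kind = "linear", rate = rate, filter = filter),
            class = "mt_clock")
}

#' @rdname linear_clock
#' @export
hvsi_clock <- function() linear_clock(18845, id = "hvsi",
                                      filter = "hvsi_transitions")

#' @rdname linear_clock
#' @param convert function mapping rho to age in years.
#' @export
custom_clock <- function(convert, id = "custom", filter = "all_accepted") {
  stopifnot(is.function(convert))
  filter <- match.arg(filter, c("all_accepted", "synonymous_only",
                                "hvsi_transitions"))
  structure(list(id = id, kind = "custom", convert = convert, filter = filter),
            class = "mt_clock")
}

#' Convert rho and sigma to a coalescence age
#'
#' Linear clocks satisfy \code{T = rho * rate} and \code{dT = sigma * rate}
#' exactly; custom clocks delegate to their conversion function, with
#' \code{dT = convert(rho + sigma) - convert(rho)}. Ages are stored in years;
#' the print method displays kiloyears rounded half-up to one decimal, the
#' convention of published age tables.
#'
#' @param rho,sigma the statistics (non-negative).
#' @param clock an \code{mt_clock}.
#' @param n number of sampled lineages (bookkeeping).
#' @return an object of class \code{mt_age} with fields \code{rho},
#'   \code{sigma}, \code{T_years}, \code{deltaT_years}, \code{n},
#'   \code{clock_id}.
#' @export
estimate_age <- function(rho, sigma = 0, clock = hvsi_clock(), n = NA_integer_) {
  stopifnot(inherits(clock, "mt_clock"), rho >= 0, sigma >= 0)
  if (clock$kind == "linear") {
    T <- rho * clock$rate
    dT <- sigma * clock$rate
  } else {
    T <- clock$convert(rho)
    dT <- clock$convert(rho + sigma) - T
  }
  structure(list(rho = rho, sigma = sigma, T_years = T, deltaT_years = dT,
                 n = as.integer(n), clock_id = clock$id),
            class = "mt_age")
}

#' Display an age in kiloyears
#' @param age an \code{mt_age}.
#' @return numeric c(T, dT) in ky, one decimal, half-up.
#' @export
age_ky <- function(age) {
  c(T = round_half_up(age$T_years / 1000, 1),
    dT = round_half_up(age$deltaT_years / 1000, 1))
}

#' @export
print.mt_age <- function(x, ...) {
  ky <- age_ky(x)
  cat(sprintf("<mt_age> rho = %.2f  sigma = %.2f  T = %.1f +/- %.1f ky  (n = %s, clock %s)\n",
              x$rho, x$sigma, ky[["T"]], ky[["dT"]],
              ifelse(is.na(x$n), "?", x$n), x$clock_id))
  invisible(x)
}

## ---- filtered clade dating ----------------------------------------------

count_link_mutations <- function(tokens, clock, mask, exclude_sites, genes, ref) {
  if (!length(tokens)) return(0L)
  v <- parse_variant_token(tokens, ref = ref)
  v <- v[!v$heteroplasmic, , drop = FALSE]                 # never dated
  v <- v[!(v$position %in% as.integer(exclude_sites)), , drop = FALSE]
  v <- apply_mask(v, mask)
  if (nrow(v) == 0L) return(0L)
  if (clock$filter == "hvsi_transitions") {
    win <- mask$hvsi_window
    # a back mutation on a genealogy link is a real transition event
    return(sum(v$kind == "transition" & v$position >= win[1] &
                 v$position <= win[2]))
  }
  if (clock$filter == "synonymous_only") {
    if (is.null(genes) || is.null(ref))
      stop("synonymous_only dating needs a gene table and a reference")
    sub <- v[v$kind %in% c("transition", "transversion"), , drop = FALSE]
    if (nrow(sub) == 0L) return(0L)
    return(sum(classify_functional_effect(sub, genes, ref) == "synonymous"))
  }
  nrow(v)
}

#' Date a clade from its genealogy
#'
#' Applies the clock's mutation filter to every link's variant list (dropping
#' heteroplasmic variants, explicitly excluded sites such as the pathogenic
#' transition 11778, and masked sites/length variants), recounts link
#' mutations, and converts the resulting rho and sigma to an age.
#'
#' @param g an \code{mt_genealogy} whose edges carry \code{mutations} token
#'   lists.
#' @param clock an \code{mt_clock}.
#' @param mask an \code{mt_mask}.
#' @param exclude_sites additional excluded positions (default 11778).
#' @param genes,ref gene table and reference, required for
#'   \code{synonymous_only} clocks.
#' @return an \code{mt_age}.
#' @export
date_clade <- function(g, clock = hvsi_clock(), mask = default_mask(),
                       exclude_sites = 11778L, genes = NULL, ref = NULL) {
  stopifnot(inherits(g, "mt_genealogy"))
  if (nrow(g$edges) > 0L && all(vapply(g$edges$mutations, is.null, logical(1))))
    stop("date_clade needs per-link variant lists ('mutations' column)")
  g$edges$m <- vapply(g$edges$mutations, count_link_mutations, integer(1),
                      clock = clock, mask = mask, exclude_sites = exclude_sites,
                      genes = genes, ref = ref)
  estimate_age(rho_statistic(g), sigma_statistic(g), clock,
               n = sum(g$multiplicity))
}

#' Build a star genealogy of profiles around a root haplotype
#'
#' The usual construction for control-region founder dating: every profile
#' becomes a pendant tip whose link carries the mutational differences to the
#' designated ancestral haplotype (variants present in the profile but not in
#' the root, plus root variants lost by the profile, recorded as back
#' mutations).
#'
#' @param profiles list of \code{mt_profile}.
#' @param root_tokens character tokens of the ancestral haplotype (default
#'   none, i.e. the reference itself).
#' @param condense_tips merge identical tips into one tip with multiplicity
#'   (default FALSE: one tip per profile).
#' @return an \code{mt_genealogy} rooted at \code{"root"}.
#' @export
genealogy_from_profiles <- function(profiles, root_tokens = character(),
                                    condense_tips = FALSE) {
  if (!length(profiles)) stop("no profiles")
  root_tokens <- if (length(root_tokens)) format_variant(parse_variant_token(root_tokens))
                 else character()
  diffs <- lapply(profiles, function(p) {
    toks <- profile_tokens(p)
    gains <- setdiff(toks, root_tokens)
    losses <- setdiff(root_tokens, toks)
    losses <- losses[!startsWith(losses, "@")]
    c(gains, if (length(losses)) paste0("@", losses) else character())
  })
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  ids <- make.unique(ids)
  if (condense_tips) {
    key <- vapply(diffs, function(d) paste(sort(d), collapse = " "), character(1))
    ord <- order(key)
    ukey <- unique(key[ord])
    first <- match(ukey, key)
    mult <- as.integer(table(factor(key, levels = ukey)))
    edges <- data.frame(parent = "root", child = ids[first],
                        stringsAsFactors = FALSE)
    edges$mutations <- diffs[first]
    genealogy(edges, root = "root",
              multiplicity = stats::setNames(mult, ids[first]))
  } else {
    edges <- data.frame(parent = "root", child = ids, stringsAsFactors = FALSE)
    edges$mutations <- diffs
    genealogy(edges, root = "root")
  }
}
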