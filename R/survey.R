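## Per-population / per-region haplogroup frequency tables.

label_node <- function(label) sub("\\*$", "", label)

#' Tabulate per-population haplogroup frequencies
#'
#' Counts carriers per (population, haplogroup), where a sample assigned to a
#' node also counts toward every ancestor of that node (a sample assigned
#' M9a1b1 counts toward M9a1b, M9a1, M9a and M9a'b). Paragroup labels
#' (\code{"X*"}) count toward X and its ancestors, never toward any child of
#' X. Samples without population metadata are excluded from the denominators
#' and reported in the \code{excluded} attribute.
#'
#' @param profiles list of \code{mt_profile}.
#' @param assignments parallel list of \code{mt_assignment}.
#' @param tree an \code{mt_hgtree}.
#' @param populations optional data frame (\code{population}, \code{region});
#'   when supplied, profiles from unlisted populations raise an error naming
#'   their sample ids, and regions are taken from it.
#' @param sizes optional named vector of per-population sample sizes;
#'   defaults to the number of included profiles per population.
#' @return a data frame of class \code{mt_freqtable} with columns
#'   \code{population}, \code{region}, \code{sample_size}, \code{haplogroup},
#'   \code{carrier_count}, \code{frequency}; attribute \code{excluded} holds
#'   the excluded-sample count.
#' @export
tabulate_frequencies <- function(profiles, assignments, tree,
                                 populations = NULL, sizes = NULL) {
  stopifnot(length(profiles) == length(assignments))
  pop <- vapply(profiles, function(p) p$population, character(1))
  reg <- vapply(profiles, function(p) p$region, character(1))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  ok <- !is.na(pop) & nzchar(pop)
  excluded <- sum(!ok)
  if (!is.null(populations)) {
    unknown <- ok & !(pop %in% populations$population)
    if (any(unknown))
      stop("unknown population for sample(s): ",
           paste(ids[unknown], collapse = ", "))
  }
  pops <- sort(unique(pop[ok]))
  if (is.null(sizes))
    sizes <- stats::setNames(as.integer(table(factor(pop[ok], levels = pops))), pops)
  region_of <- function(pp) {
    if (!is.null(populations)) {
      r <- populations$region[match(pp, populations$population)]
      if (!is.na(r)) return(r)
    }
    r <- unique(reg[ok & pop == pp & !is.na(reg)])
    if (length(r)) r[1] else NA_character_
  }

  nodes <- setdiff(tree$nodes, tree$root)
  counts <- matrix(0L, nrow = length(pops), ncol = length(nodes),
                   dimnames = list(pops, nodes))
  for (i in which(ok)) {
    lab <- assignments[[i]]$label
    if (is.na(lab %||% NA)) next
    node <- label_node(lab)
    if (!node %in% tree$nodes) next
    for (anc in setdiff(tree_path(tree, node), tree$root))
      counts[pop[i], anc] <- counts[pop[i], anc] + 1L
  }

  out <- do.call(rbind, lapply(pops, function(pp) {
    data.frame(population = pp, region = region_of(pp),
               sample_size = as.integer(sizes[[pp]]),
               haplogroup = nodes,
               carrier_count = as.integer(counts[pp, ]),
               frequency = as.numeric(counts[pp, ]) / as.integer(sizes[[pp]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("mt_freqtable", "data.frame")
  out
}

#' Regional breakdown of a haplogroup's carriers
#'
#' Counts carriers of a haplogroup (including carriers assigned to its
#' descendants; paragroup labels count toward their node) per region.
#'
#' @param profiles list of \code{mt_profile}.
#' @param assignments parallel list of \code{mt_assignment}.
#' @param haplogroup node name.
#' @param tree an \code{mt_hgtree}.
#' @return named integer vector (region -> count); regions with zero carriers
#'   are omitted, so the values sum to the total carrier count.
#' @export
regional_breakdown <- function(profiles, assignments, haplogroup, tree) {
  stopifnot(length(profiles) == length(assignments),
            haplogroup %in% tree$nodes)
  hit <- vapply(seq_along(profiles), function(i) {
    lab <- assignments[[i]]$label
    if (is.na(lab %||% NA)) return(FALSE)
    node <- label_node(lab)
    node %in% tree$nodes && haplogroup %in% tree_path(tree, node)
  }, logical(1))
  if (!any(hit)) return(stats::setNames(integer(), character()))
  reg <- vapply(profiles[hit], function(p)
    if (is.na(p$region)) "unknown" else p$region, character(1))
  tab <- table(reg)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a frequency table as TSV
#' @param x an \code{mt_freqtable}.
#' @param path output file.
#' @param comments character vector written as leading "#" lines.
#' @export
write_frequency_table <- function(x, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste0("# excluded_samples\t", attr(x, "excluded") %||% 0L), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
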