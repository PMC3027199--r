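#' Export and re-import a network as plain text
#'
#' Writes a node table (id, count, observed flag, region tallies, state
#' vector) and an edge table (endpoints, length, mutated-position labels) in
#' a stable, documented text format. \code{read_network} reproduces the
#' exported network exactly.
#'
#' @param net an \code{mt_network}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  h <- net$haplotypes
  writeLines(c("# mtlineage network v1",
               paste0("epsilon\t", format(net$epsilon, digits = 15))), con)
  writeLines("[positions]", con)
  for (p in colnames(h$states))
    writeLines(paste0(p, "\t", format(net$weights[[p]], digits = 15)), con)
  writeLines("[nodes]", con)
  writeLines("id\tcount\tobserved\tregions\tstates", con)
  for (id in rownames(h$states)) {
    rg <- h$regions[[id]]
    rgs <- if (length(rg)) paste(paste0(names(rg), "=", rg), collapse = ";") else ""
    writeLines(paste(id, h$count[[id]], ifelse(h$observed[[id]], 1L, 0L), rgs,
                     paste(h$states[id, ], collapse = ";"), sep = "\t"), con)
  }
  writeLines("[edges]", con)
  writeLines("from\tto\tlength\tlabels", con)
  for (r in seq_len(nrow(net$links)))
    writeLines(paste(net$links$from[r], net$links$to[r],
                     format(net$links$length[r], digits = 15),
                     net$links$labels[r], sep = "\t"), con)
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  sec <- function(name) {
    i <- match(paste0("[", name, "]"), lines)
    if (is.na(i)) stop("network file misses section [", name, "]")
    j <- grep("^\\[", lines)
    j <- j[j > i]
    end <- if (length(j)) min(j) - 1L else length(lines)
    if (end < i + 1L) return(character())
    lines[(i + 1L):end]
  }
  eps <- as.numeric(sub("^epsilon\t", "", grep("^epsilon\t", lines, value = TRUE)[1]))
  posl <- strsplit(sec("positions"), "\t")
  positions <- vapply(posl, `[`, character(1), 1)
  weights <- stats::setNames(as.numeric(vapply(posl, `[`, character(1), 2)), positions)

  nl <- sec("nodes"); nl <- nl[-1]                    # drop header
  parts <- strsplit(nl, "\t")
  ids <- vapply(parts, `[`, character(1), 1)
  count <- stats::setNames(as.integer(vapply(parts, `[`, character(1), 2)), ids)
  observed <- stats::setNames(vapply(parts, `[`, character(1), 3) == "1", ids)
  regions <- stats::setNames(lapply(parts, function(p) {
    f <- p[4]
    if (is.na(f) || !nzchar(f)) return(stats::setNames(integer(), character()))
    kv <- strsplit(strsplit(f, ";")[[1]], "=")
    stats::setNames(as.integer(vapply(kv, `[`, character(1), 2)),
                    vapply(kv, `[`, character(1), 1))
  }), ids)
  if (length(positions)) {
    states <- t(vapply(parts, function(p) {
      s <- strsplit(p[5], ";", fixed = TRUE)[[1]]
      if (is.na(p[5]) || length(s) != length(positions))
        stop("node state vector of wrong length in ", path)
      s
    }, character(length(positions))))
  } else {
    states <- matrix("", nrow = length(ids), ncol = 0L)
  }
  rownames(states) <- ids; colnames(states) <- positions

  el <- sec("edges"); el <- el[-1]
  if (length(el)) {
    ep <- strsplit(el, "\t")
    links <- data.frame(from = vapply(ep, `[`, character(1), 1),
                        to = vapply(ep, `[`, character(1), 2),
                        length = as.numeric(vapply(ep, `[`, character(1), 3)),
                        labels = vapply(ep, function(p) ifelse(is.na(p[4]), "", p[4]),
                                        character(1)),
                        stringsAsFactors = FALSE)
  } else {
    links <- data.frame(from = character(), to = character(),
                        length = numeric(), labels = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(haplotypes = structure(list(states = states, count = count,
                                             observed = observed,
                                             regions = regions),
                                        class = "mt_haplotypes"),
                 links = links, epsilon = eps, weights = weights),
            class = "mt_network")
}
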