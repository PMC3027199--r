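#' Read and write haplogroup definition files
#'
#' Plain-text tree serialization: one node per line, depth encoded by leading
#' tab characters, then the node name, then (after whitespace) a
#' comma-separated list of defining variant tokens. Lines starting with
#' \code{"#"} and blank lines are ignored. A node's parent is the most recent
#' shallower node above it. The format round-trips through
#' \code{write_haplogroup_tree}.
#'
#' @param path file path.
#' @return an \code{mt_hgtree}.
#' @export
read_haplogroup_tree <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  if (!any(keep)) stop("no root: definition file ", path, " holds no nodes")
  name <- character(); parent <- character(); definers <- character()
  stack <- character()   # stack[d+1] = current node at depth d
  lineno <- which(keep)
  for (i in seq_along(lineno)) {
    ln <- lines[lineno[i]]
    depth <- nchar(sub("^(\t*).*$", "\\1", ln))
    body <- trimws(sub("^\t*", "", ln))
    fields <- strsplit(body, "[[:space:]]+", fixed = FALSE)[[1]]
    nm <- fields[1]
    toks <- if (length(fields) > 1L) paste(fields[-1], collapse = " ") else ""
    if (nm %in% name)
      stop("line ", lineno[i], ": duplicate node '", nm, "'")
    if (depth > length(stack))
      stop("line ", lineno[i], ": indentation jumps over a level at '", nm, "'")
    if (depth == 0L && length(stack))
      stop("line ", lineno[i], ": second root '", nm, "'")
    par <- if (depth == 0L) NA_character_ else stack[depth]
    name <- c(name, nm); parent <- c(parent, par); definers <- c(definers, toks)
    stack <- c(stack[seq_len(depth)], nm)
  }
  haplogroup_tree(data.frame(name = name, parent = parent, definers = definers,
                             stringsAsFactors = FALSE))
}

#' @rdname read_haplogroup_tree
#' @param tree an \code{mt_hgtree}.
#' @param comments character vector written as leading "#" lines.
#' @export
write_haplogroup_tree <- function(tree, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  emit <- function(nm, depth) {
    toks <- tree$definers[[nm]]
    field <- if (length(toks)) paste0("\t", paste(toks, collapse = ","))
             else if (isTRUE(tree$structural[[nm]])) "\t-"
             else ""
    writeLines(paste0(strrep("\t", depth), nm, field), con)
    for (ch in tree_children(tree, nm)) emit(ch, depth + 1L)
  }
  emit(tree$root, 0L)
  invisible(path)
}

#' Load a haplogroup definition tree
#'
#' \code{load_definitions()} with no argument loads the packaged default
#' M9a'b nomenclature; \code{load_definitions("f1c")} loads the F1c
#' control-region fixture; any other value is taken as a file path.
#'
#' The default M9a'b file encodes the published definitions
#' (M9a = 14308 + 16234, M9a1 = 1041, M9a1a = 16316 (control region only),
#' M9a4 = 6366, M9a5 = 385 + 8155 + 12237, M9b diagnostic 4491) and marks the
#' remaining branch definers, which are known only from tree figures, as
#' synthetic stand-ins that users should edit to their nomenclature build.
#'
#' @param path \code{NULL}, \code{"m9ab"}, \code{"f1c"}, or a file path.
#' @return an \code{mt_hgtree}.
#' @export
load_definitions <- function(path = NULL) {
  if (is.null(path) || identical(path, "m9ab"))
    path <- system.file("extdata", "m9ab_definitions.txt", package = "mtlineage",
                        mustWork = TRUE)
  else if (identical(path, "f1c"))
    path <- system.file("extdata", "f1c_definitions.txt", package = "mtlineage",
                        mustWork = TRUE)
  read_haplogroup_tree(path)
}
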