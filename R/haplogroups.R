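## Haplogroup nomenclature trees and motif-based assignment.
##
## A tree node carries the variants that define it relative to its parent;
## the cumulative motif of a node is the union of definers along the
## root->node path, with back-mutation definers ("@P") cancelling earlier
## gains at the same position.

CONTROL_REGION <- list(c(16024L, 16569L), c(1L, 576L))

is_control_position <- function(pos) in_intervals(pos, CONTROL_REGION)

#' Construct a haplogroup definition tree
#'
#' @param nodes data frame with columns \code{name}, \code{parent}
#'   (\code{NA} for the root) and \code{definers} (space- or comma-separated
#'   variant tokens; the root and only the root may have none).
#' @return an object of class \code{mt_hgtree}.
#' @export
haplogroup_tree <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("name", "parent", "definers")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) stop("node table misses column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(nodes$name))
    stop("duplicate haplogroup name(s): ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  root <- nodes$name[is.na(nodes$parent) | nodes$parent == ""]
  if (length(root) == 0L) stop("no root: every node has a parent")
  if (length(root) > 1L) stop("multiple roots: ", paste(root, collapse = ", "))
  orphan <- setdiff(stats::na.omit(nodes$parent), c(nodes$name, ""))
  if (length(orphan)) stop("orphan parent reference(s): ", paste(orphan, collapse = ", "))

  ## "-" flags a deliberately definer-less structural node (e.g. a clade
  ## whose own diagnostic sites are carried by the candidate screen, not the
  ## tree); such nodes organise the nomenclature but are never themselves
  ## assignment targets
  structural <- trimws(as.character(nodes$definers)) == "-"
  definers <- lapply(seq_len(nrow(nodes)), function(i) {
    if (structural[i]) return(character())
    toks <- strsplit(trimws(as.character(nodes$definers[i] %||% "")),
                     "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks)) format_variant(parse_variant_token(toks)) else character()
  })
  names(definers) <- nodes$name
  names(structural) <- nodes$name
  empty <- lengths(definers) == 0L & nodes$name != root & !structural
  if (any(empty))
    stop("non-root node(s) without defining variants: ",
         paste(nodes$name[empty], collapse = ", "),
         " (use '-' to flag a structural node)")

  tree <- structure(list(nodes = nodes$name, parent = stats::setNames(nodes$parent, nodes$name),
                         definers = definers, structural = structural,
                         root = root),
                    class = "mt_hgtree")
  # cycle / connectivity check: every node must reach the root
  for (nm in tree$nodes) {
    seen <- character(); cur <- nm
    while (!is.na(cur) && cur != "" && cur != root) {
      if (cur %in% seen) stop("cycle in tree at node ", cur)
      seen <- c(seen, cur)
      cur <- tree$parent[[cur]]
      if (is.null(cur)) stop("disconnected node ", nm)
    }
  }
  tree
}

#' @export
print.mt_hgtree <- function(x, ...) {
  cat("<mt_hgtree>", length(x$nodes), "nodes, root", x$root, "\n")
  invisible(x)
}

tree_children <- function(tree, name) tree$nodes[!is.na(tree$parent[tree$nodes]) &
                                                   tree$parent[tree$nodes] == name]

## ancestors from root down to (and including) name
tree_path <- function(tree, name) {
  path <- character()
  cur <- name
  while (!is.na(cur) && cur != "") {
    path <- c(cur, path)
    cur <- tree$parent[[cur]]
  }
  path
}

tree_depth <- function(tree, name) length(tree_path(tree, name)) - 1L

#' Deepest common ancestor of a set of haplogroup names
#' @param tree an \code{mt_hgtree}.
#' @param names node names.
#' @return a single node name.
#' @export
deepest_common_ancestor <- function(tree, names) {
  paths <- lapply(names, tree_path, tree = tree)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

#' Cumulative defining motif of a node
#'
#' Union of defining variants along the root-to-node path; a back-mutation
#' definer \code{@P} cancels a variant gained at P higher up (and is itself
#' recorded as a requirement that P be absent).
#'
#' @param tree an \code{mt_hgtree}.
#' @param name node name.
#' @return character vector of canonical tokens; back-mutation requirements
#'   keep their \code{@} prefix.
#' @export
cumulative_motif <- function(tree, name) {
  if (!name %in% tree$nodes) stop("unknown haplogroup: ", name)
  motif <- character()
  for (nm in tree_path(tree, name)) {
    for (tok in tree$definers[[nm]]) {
      if (startsWith(tok, "@")) {
        pos <- parse_variant_token(tok)$position
        gained <- vapply(motif, function(t) parse_variant_token(t)$position == pos,
                         logical(1))
        motif <- motif[!gained]
        motif <- c(motif, tok)
      } else motif <- c(motif, tok)
    }
  }
  unique(motif)
}

## --- motif/token matching against a profile ----------------------------

## Does a profile carry a single motif token?  Substitution tokens match by
## position (literature HVS-I lists are bare positions, so transition vs
## transversion spelling is not enforced unless both sides state a base);
## indel tokens must match kind (and inserted string); a declared back
## mutation "@P" in the profile satisfies a positive token at P (the lineage
## passed through the variant); a "@P" token requires P to be effectively
## absent.
token_in_profile <- function(tok, p) {
  tv <- parse_variant_token(tok)
  v <- p$variants
  at <- v[v$position == tv$position, , drop = FALSE]
  if (tv$back) {
    if (nrow(at) == 0L) return(TRUE)
    return(all(at$back | at$kind %in% c("insertion", "deletion")))
  }
  if (nrow(at) == 0L) return(FALSE)
  if (any(at$back)) return(TRUE)
  if (tv$kind %in% c("insertion", "deletion")) {
    hit <- at$kind == tv$kind & (tv$kind != "insertion" | at$derived == tv$derived)
    return(any(hit))
  }
  sub <- at[at$kind %in% c("transition", "transversion"), , drop = FALSE]
  if (nrow(sub) == 0L) return(FALSE)
  if (tv$kind == "transversion")
    any(sub$kind == "transition" | sub$derived == tv$derived |
          sub$derived == "")
  else TRUE
}

motif_missing <- function(motif, p) motif[!vapply(motif, token_in_profile, logical(1), p = p)]

#' Screen a profile as a haplogroup M9a'b candidate
#'
#' The survey screen: a profile is a candidate when it carries the full
#' control-region motif 16223-16234-16362-153 (all four transitions) and/or a
#' transition at coding-region diagnostic site 3394 or 4491.
#'
#' @param p an \code{mt_profile}.
#' @return logical.
#' @export
screen_m9ab_candidate <- function(p) {
  has <- function(tok) token_in_profile(tok, p)
  all(vapply(c("16223", "16234", "16362", "153"), has, logical(1))) ||
    has("3394") || has("4491")
}

assignment_result <- function(label, status, matched = character(),
                              missing = character(), distance = NA_integer_,
                              control_region_only = FALSE) {
  structure(list(label = label, status = status, matched = matched,
                 missing = missing, distance_to_nearest = distance,
                 control_region_only = control_region_only),
            class = "mt_assignment")
}

#' @export
print.mt_assignment <- function(x, ...) {
  cat("<mt_assignment>", x$label, sprintf("(%s)", x$status),
      if (x$control_region_only) "[control-region-only definer]" else "", "\n")
  invisible(x)
}

## name of the focal clade used for the screened-only paragroup label: the
## root's single child when unique, else the root itself
focal_clade <- function(tree) {
  ch <- tree_children(tree, tree$root)
  if (length(ch) == 1L) ch else tree$root
}

#' Assign a profile to the deepest matching haplogroup
#'
#' Returns the deepest node whose cumulative motif is fully present in the
#' profile (declared back mutations both satisfy and cancel motif variants as
#' appropriate). If the profile additionally carries partial - but incomplete
#' - evidence for some child of that node, its placement below the node is
#' ambiguous and the paragroup form \code{"node*"} is reported; a profile
#' carrying no child-defining variant is reported as a plain member of the
#' node. If no node beyond the root matches, the profile is labelled with the
#' focal clade's paragroup form when the candidate screen passes
#' (status \code{screened_only}) and is otherwise \code{unassigned}.
#'
#' Assignments that rest solely on control-region definers are flagged
#' \code{control_region_only}, echoing the caveat that such haplogroup
#' definitions are weaker than coding-region ones.
#'
#' @param p an \code{mt_profile}.
#' @param tree an \code{mt_hgtree}.
#' @param screen candidate screen function (profile -> logical), used for the
#'   fallback label; \code{NULL} disables the screened-only fallback.
#' @return an \code{mt_assignment}.
#' @export
assign_haplogroup <- function(p, tree, screen = screen_m9ab_candidate) {
  ## structural (definer-less) nodes are never assignment targets
  non_root <- setdiff(tree$nodes[!tree$structural[tree$nodes]], tree$root)
  missing <- lapply(non_root, function(nm) motif_missing(cumulative_motif(tree, nm), p))
  names(missing) <- non_root
  full <- non_root[lengths(missing) == 0L]

  if (length(full) == 0L) {
    dist <- if (length(non_root)) min(lengths(missing)) else NA_integer_
    if (!is.null(screen) && screen(p))
      return(assignment_result(paste0(focal_clade(tree), "*"), "screened_only",
                               distance = dist))
    return(assignment_result(NA_character_, "unassigned", distance = dist))
  }

  depth <- vapply(full, tree_depth, integer(1), tree = tree)
  nmot <- vapply(full, function(nm) length(cumulative_motif(tree, nm)), integer(1))
  best <- full[order(-depth, -nmot, full)][1]
  motif <- cumulative_motif(tree, best)
  cr_only <- {
    own <- tree$definers[[best]]
    length(own) > 0L &&
      all(is_control_position(parse_variant_token(sub("^@", "", own))$position))
  }

  child_partial <- any(vapply(tree_children(tree, best), function(ch) {
    any(vapply(tree$definers[[ch]], token_in_profile, logical(1), p = p))
  }, logical(1)))

  if (child_partial)
    assignment_result(paste0(best, "*"), "paragroup", matched = motif,
                      distance = 0L, control_region_only = cr_only)
  else
    assignment_result(best, "exact", matched = motif, distance = 0L,
                      control_region_only = cr_only)
}

## Hamming-type distance between two profiles restricted to the HVS-I window
## plus any explicitly supplied coding sites; absent = ancestral state.
profile_distance <- function(a, b, mask = default_mask(), coding_sites = NULL) {
  win <- mask$hvsi_window
  state <- function(p) {
    v <- apply_mask(p$variants, mask)
    keep <- (v$position >= win[1] & v$position <= win[2]) |
      v$position %in% as.integer(coding_sites %||% integer())
    v <- v[keep & !v$back, , drop = FALSE]
    stats::setNames(paste(v$kind, v$derived), as.character(v$position))
  }
  sa <- state(a); sb <- state(b)
  pos <- union(names(sa), names(sb))
  mismatch <- function(pp) {
    x <- sa[pp]; y <- sb[pp]
    if (is.na(x) || is.na(y)) return(TRUE)        # present in only one
    if (identical(unname(x), unname(y))) return(FALSE)
    # bare transition vs transversion spelling at one position still differs
    TRUE
  }
  sum(vapply(pos, mismatch, logical(1)))
}

#' Assign by matching and near-matching against classified lineages
#'
#' Compares a profile to already-classified haplotypes on the HVS-I window
#' (plus any supplied coding sites). An identical haplotype inherits its label
#' with status \code{exact}; otherwise the nearest classified haplotype within
#' Hamming distance \code{k} (default 1, i.e. one-step neighbours) donates its
#' label with status \code{near_match}. When several labels tie at the minimal
#' distance the conservative fallback is the deepest common ancestor of the
#' tied labels, reported in paragroup form.
#'
#' @param p an \code{mt_profile}.
#' @param classified list of \code{list(profile = , label = )}.
#' @param tree an \code{mt_hgtree} (for the tie-break ancestor).
#' @param k maximal near-match distance.
#' @param mask an \code{mt_mask}.
#' @param coding_sites coding positions additionally compared.
#' @return an \code{mt_assignment}.
#' @export
near_match_assign <- function(p, classified, tree, k = 1L,
                              mask = default_mask(), coding_sites = NULL) {
  if (!length(classified)) stop("no classified lineages to match against")
  d <- vapply(classified, function(cl)
    profile_distance(p, cl$profile, mask = mask, coding_sites = coding_sites),
    numeric(1))
  labels <- vapply(classified, function(cl) cl$label, character(1))
  dmin <- min(d)
  tied <- unique(labels[d == dmin])
  if (dmin == 0) {
    if (length(tied) == 1L)
      return(assignment_result(tied, "exact", distance = 0L))
  } else if (dmin > k) {
    return(assignment_result(NA_character_, "unassigned",
                             distance = as.integer(dmin)))
  }
  if (length(tied) == 1L)
    return(assignment_result(tied, "near_match", distance = as.integer(dmin)))
  dca <- deepest_common_ancestor(tree, sub("\\*$", "", tied))
  assignment_result(paste0(dca, "*"), "paragroup", distance = as.integer(dmin))
}
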