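## Haplotype condensation and median-joining networks.
##
## Haplotypes are state vectors over a shared position set: "0" is the
## ancestral (reference) state, "1" a transition, a base letter a
## transversion, "d"/"+S" indels, "R"/"Y" heteroplasmic states. Networks are
## built from epsilon-relaxed minimum spanning networks with inferred
## (quasi-)median nodes.

variant_state <- function(kind, derived, heteroplasmic, back) {
  if (back) return("0")
  if (kind == "transition") return(if (heteroplasmic) derived else "1")
  if (kind == "transversion") return(derived)
  if (kind == "deletion") return("d")
  paste0("+", derived)
}

state_token <- function(pos, state) {
  switch(state,
         "0" = stop("ancestral state has no token"),
         "1" = as.character(pos),
         paste0(pos, state))
}

profile_states <- function(p, positions) {
  st <- rep("0", length(positions))
  names(st) <- as.character(positions)
  v <- p$variants
  v <- v[v$position %in% positions, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    key <- as.character(v$position[i])
    s <- variant_state(v$kind[i], v$derived[i], v$heteroplasmic[i], v$back[i])
    st[key] <- if (st[key] == "0") s else paste(sort(c(st[key], s)), collapse = "&")
  }
  st
}

#' Condense profiles into haplotypes
#'
#' Reduces profiles to state vectors over the analyzed position set and
#' merges identical vectors, summing counts and per-region tallies. Output
#' order is deterministic (lexicographic by state vector); observed
#' haplotypes receive ids \code{H1}, \code{H2}, ... in that order.
#'
#' @param profiles list of \code{mt_profile}.
#' @param positions analyzed positions; defaults to the union of variant
#'   positions after masking.
#' @param mask optional \code{mt_mask} applied before condensation.
#' @return an object of class \code{mt_haplotypes}: a state matrix plus
#'   \code{count}, \code{observed} and \code{regions} metadata.
#' @export
condense <- function(profiles, positions = NULL, mask = NULL) {
  if (!length(profiles)) stop("no profiles to condense")
  if (!is.null(mask)) profiles <- lapply(profiles, apply_mask, mask = mask)
  if (is.null(positions))
    positions <- sort(unique(unlist(lapply(profiles, function(p) p$variants$position))))
  positions <- sort(unique(as.integer(positions)))
  sv <- vapply(profiles, profile_states, character(length(positions)),
               positions = positions)
  states <- if (length(positions) == 1L) matrix(sv, ncol = 1L)
            else if (length(positions) == 0L) matrix("", nrow = length(profiles),
                                                     ncol = 0L)
            else t(sv)
  colnames(states) <- as.character(positions)
  key <- apply(states, 1L, paste, collapse = "\r")
  ord <- order(key)
  ukey <- unique(key[ord])
  idx <- match(key, ukey)
  n <- length(ukey)
  st <- states[match(ukey, key), , drop = FALSE]
  ids <- paste0("H", seq_len(n))
  rownames(st) <- ids
  count <- as.integer(tabulate(idx, n))
  regions <- lapply(seq_len(n), function(k) {
    rg <- vapply(profiles[idx == k], function(p)
      if (is.na(p$region)) "unknown" else p$region, character(1))
    tab <- table(rg)
    stats::setNames(as.integer(tab), names(tab))
  })
  structure(list(states = st, count = stats::setNames(count, ids),
                 observed = stats::setNames(rep(TRUE, n), ids),
                 regions = stats::setNames(regions, ids)),
            class = "mt_haplotypes")
}

#' @export
print.mt_haplotypes <- function(x, ...) {
  cat("<mt_haplotypes>", nrow(x$states), "haplotypes over",
      ncol(x$states), "positions;", sum(x$count), "samples\n")
  invisible(x)
}

make_weights <- function(positions, weights = NULL, default = 10) {
  w <- stats::setNames(rep(as.numeric(default), length(positions)),
                       as.character(positions))
  if (!is.null(weights)) {
    if (is.null(names(weights))) stop("weights must be named by position")
    w[names(weights)] <- as.numeric(weights)
  }
  if (any(w <= 0)) stop("position weights must be positive")
  w
}

#' Weighted mismatch distance between haplotype state vectors
#'
#' Sum of position weights over positions where the two state vectors differ;
#' symmetric and zero iff the vectors are equal.
#'
#' @param a,b state vectors (named by position) or single-row matrices.
#' @param weights named positive weights; default 10 per position.
#' @return a non-negative number.
#' @export
weighted_distance <- function(a, b, weights = NULL) {
  a <- drop(a); b <- drop(b)
  if (length(a) != length(b)) stop("state vectors over different position sets")
  w <- make_weights(names(a) %||% seq_along(a), weights)
  sum(w[a != b])
}

state_dist_matrix <- function(states, weights) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(weights[states[i, ] != states[j, ]])
  }
  d
}

## epsilon-relaxed minimum spanning network over a state matrix.
## Repeatedly: let sigma be the smallest distance joining two distinct
## components; retain ALL between-component links (components as of the start
## of the step) with distance <= sigma + epsilon; merge; stop when connected.
msn_links <- function(states, epsilon = 0, weights) {
  n <- nrow(states)
  from <- integer(); to <- integer(); len <- numeric()
  if (n < 2L) return(data.frame(from = from, to = to, length = len))
  d <- state_dist_matrix(states, weights)
  comp <- seq_len(n)
  while (length(unique(comp)) > 1L) {
    cross <- outer(comp, comp, "!=") & upper.tri(d)
    sigma <- min(d[cross])
    take <- which(cross & d <= sigma + epsilon, arr.ind = TRUE)
    for (r in seq_len(nrow(take))) {
      i <- take[r, 1]; j <- take[r, 2]
      from <- c(from, i); to <- c(to, j); len <- c(len, d[i, j])
    }
    for (r in seq_len(nrow(take))) {        # merge after collecting the class
      ci <- comp[take[r, 1]]; cj <- comp[take[r, 2]]
      comp[comp == cj] <- ci
    }
  }
  data.frame(from = from, to = to, length = len)
}

## per-position majority state of three vectors; positions where all three
## states differ are ties and expand into one vector per tied state
## (quasi-median expansion)
quasi_medians <- function(u, v, w, max_expand = 64L) {
  m <- ifelse(u == v | u == w, u, ifelse(v == w, v, NA))
  ties <- which(is.na(m))
  if (!length(ties)) return(list(m))
  grids <- lapply(ties, function(k) unique(c(u[k], v[k], w[k])))
  if (prod(lengths(grids)) > max_expand)
    stop("quasi-median expansion exceeds ", max_expand, " combinations")
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(r) {
    x <- m
    x[ties] <- as.character(unlist(combos[r, ]))
    names(x) <- names(u)
    x
  })
}

## All new (quasi-)median vectors over triples of rows of `states`, excluding
## vectors already present. A per-position majority median of three distinct
## vectors is always a strict connection saving for its generating triple, so
## majority medians are added outright; tie positions (three distinct states,
## only possible with multi-state characters) expand into quasi-medians,
## which are kept when they save connection cost. Vectorized over triples via
## per-column integer coding; returns a character matrix (possibly 0 rows).
median_candidates <- function(states, weights, new_rows = NULL) {
  n <- nrow(states)
  if (n < 3L) return(NULL)
  levels_by_col <- lapply(seq_len(ncol(states)), function(j) unique(states[, j]))
  M <- vapply(seq_len(ncol(states)), function(j)
    match(states[, j], levels_by_col[[j]]), integer(n))
  if (!is.matrix(M)) M <- matrix(M, nrow = n)

  tri <- utils::combn(n, 3L)
  if (!is.null(new_rows)) {
    keep <- tri[1, ] %in% new_rows | tri[2, ] %in% new_rows | tri[3, ] %in% new_rows
    tri <- tri[, keep, drop = FALSE]
  }
  if (!ncol(tri)) return(NULL)
  A <- M[tri[1, ], , drop = FALSE]
  B <- M[tri[2, ], , drop = FALSE]
  C <- M[tri[3, ], , drop = FALSE]
  med <- A
  med[A != B & A != C] <- NA_integer_
  bc <- B == C & A != B
  med[bc] <- B[bc]

  have <- apply(states, 1L, paste, collapse = "\r")
  decode <- function(row) {
    vapply(seq_along(row), function(j) levels_by_col[[j]][row[j]], character(1))
  }
  out <- list(); okey <- character()
  tied <- which(apply(med, 1L, anyNA))
  for (r in setdiff(seq_len(nrow(med)), tied)) {
    m <- decode(med[r, ])
    key <- paste(m, collapse = "\r")
    if (key %in% have || key %in% okey) next
    out <- c(out, list(m)); okey <- c(okey, key)
  }
  for (r in tied) {                      # quasi-median expansion on ties
    t3 <- tri[, r]
    u <- states[t3[1], ]; v <- states[t3[2], ]; w <- states[t3[3], ]
    pair_cost <- sum(weights[u != v]) + sum(weights[u != w]) + sum(weights[v != w])
    for (m in quasi_medians(u, v, w)) {
      key <- paste(m, collapse = "\r")
      if (key %in% have || key %in% okey) next
      cost <- sum(weights[u != m]) + sum(weights[v != m]) + sum(weights[w != m])
      if (cost < pair_cost) { out <- c(out, list(m)); okey <- c(okey, key) }
    }
  }
  if (!length(out)) return(NULL)
  mat <- do.call(rbind, out)
  colnames(mat) <- colnames(states)
  mat
}

finish_network <- function(states, count, observed, regions, links, weights,
                           epsilon) {
  ids <- rownames(states)
  pos <- colnames(states)
  labels <- vapply(seq_len(nrow(links)), function(r) {
    a <- states[links$from[r], ]; b <- states[links$to[r], ]
    diffp <- which(a != b)
    paste(vapply(diffp, function(k) {
      if (a[k] == "0") state_token(pos[k], b[k])
      else if (b[k] == "0") state_token(pos[k], a[k])
      else paste0(pos[k], ":", a[k], ">", b[k])
    }, character(1)), collapse = " ")
  }, character(1))
  links_out <- data.frame(from = ids[links$from], to = ids[links$to],
                          length = links$length, labels = labels,
                          stringsAsFactors = FALSE)
  links_out <- links_out[order(links_out$from, links_out$to), , drop = FALSE]
  rownames(links_out) <- NULL
  structure(list(haplotypes = structure(list(states = states, count = count,
                                             observed = observed,
                                             regions = regions),
                                        class = "mt_haplotypes"),
                 links = links_out, epsilon = epsilon, weights = weights),
            class = "mt_network")
}

#' Minimum spanning network
#'
#' Kruskal-style construction over increasing distance classes: at each step
#' every link whose distance is within \code{epsilon} of the smallest
#' distance joining two distinct components (components as of the start of
#' the step) is retained, not just one link per merge, so all equally short
#' alternative connections appear. The result is connected and contains every
#' minimum spanning tree of the haplotypes.
#'
#' @param haplotypes an \code{mt_haplotypes} (see \code{\link{condense}}).
#' @param epsilon non-negative relaxation parameter (default 0).
#' @param weights named per-position weights (default 10 each).
#' @return an object of class \code{mt_network}.
#' @export
minimum_spanning_network <- function(haplotypes, epsilon = 0, weights = NULL) {
  st <- haplotypes$states
  w <- make_weights(colnames(st), weights)
  links <- msn_links(st, epsilon, w)
  finish_network(st, haplotypes$count, haplotypes$observed, haplotypes$regions,
                 links, w, epsilon)
}

#' Median-joining network
#'
#' Iterates between building the epsilon-relaxed minimum spanning network
#' over the current node set and adding inferred (quasi-)median vectors of
#' node triples until no further median can be added, then removes obsolete
#' median nodes: unobserved nodes of degree at most two that lie on no
#' shortest connection between observed haplotypes (removal runs to a fixed
#' point, rebuilding the network after each batch). Median nodes are labelled
#' \code{mv1}, \code{mv2}, ... in canonical (lexicographic) order so output
#' is reproducible regardless of input order.
#'
#' @inheritParams minimum_spanning_network
#' @param max_iter iteration cap for the median-addition loop.
#' @param max_nodes cap on the total node count during median inference.
#' @return an \code{mt_network} whose unobserved nodes carry count 0.
#' @export
median_joining <- function(haplotypes, epsilon = 0, weights = NULL,
                           max_iter = 100L, max_nodes = 2000L) {
  st <- haplotypes$states
  w <- make_weights(colnames(st), weights)
  n_obs <- nrow(st)
  observed <- rep(TRUE, n_obs)

  ## 1) grow the node set to the (quasi-)median closure
  new_rows <- seq_len(n_obs)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("median inference did not converge within ", max_iter, " iterations")
    cand <- median_candidates(st, w, new_rows = if (iter == 1L) NULL else new_rows)
    if (is.null(cand) || !nrow(cand)) break
    first_new <- nrow(st) + 1L
    st <- rbind(st, cand)
    observed <- c(observed, rep(FALSE, nrow(cand)))
    if (nrow(st) > max_nodes)
      stop("median inference exceeded max_nodes = ", max_nodes)
    new_rows <- first_new:nrow(st)
  }

  ## 2) prune obsolete medians against the epsilon-relaxed MSN, to fixed point
  repeat {
    links <- msn_links(st, epsilon, w)
    deg <- tabulate(c(links$from, links$to), nbins = nrow(st))
    drop <- logical(nrow(st))
    for (x in which(!observed)) {
      if (deg[x] > 2L) next
      on_geo <- FALSE
      obs_idx <- which(observed)
      for (a in obs_idx) {
        dax <- sum(w[st[a, ] != st[x, ]])
        for (b in obs_idx) {
          if (b <= a) next
          dab <- sum(w[st[a, ] != st[b, ]])
          dxb <- sum(w[st[x, ] != st[b, ]])
          if (isTRUE(all.equal(dax + dxb, dab))) { on_geo <- TRUE; break }
        }
        if (on_geo) break
      }
      if (!on_geo) drop[x] <- TRUE
    }
    if (!any(drop)) break
    st <- st[!drop, , drop = FALSE]
    observed <- observed[!drop]
  }

  ## 3) canonical ids for medians, final network
  med <- which(!observed)
  med_keys <- apply(st[med, , drop = FALSE], 1L, paste, collapse = "\r")
  med_ord <- med[order(med_keys)]
  perm <- c(which(observed), med_ord)
  st <- st[perm, , drop = FALSE]
  observed <- observed[perm]
  ids <- c(rownames(haplotypes$states),
           if (length(med)) paste0("mv", seq_along(med)) else character())
  rownames(st) <- ids
  count <- stats::setNames(c(haplotypes$count, rep(0L, length(med))), ids)
  obs <- stats::setNames(observed, ids)
  regions <- c(haplotypes$regions,
               stats::setNames(rep(list(stats::setNames(integer(), character())),
                                   length(med)),
                               ids[!observed]))
  links <- msn_links(st, epsilon, w)
  finish_network(st, count, obs, regions, links, w, epsilon)
}

#' @export
print.mt_network <- function(x, ...) {
  h <- x$haplotypes
  cat("<mt_network>", nrow(h$states), "nodes (",
      sum(h$observed), "observed,", sum(!h$observed), "median ),",
      nrow(x$links), "links, epsilon", x$epsilon, "\n")
  invisible(x)
}

total_link_length <- function(net) sum(net$links$length)
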