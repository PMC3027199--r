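## Independent oracles used to cross-check the package's algorithms.
## These deliberately reimplement the same mathematical definitions with
## different code paths (igraph for connectivity, table() for majorities,
## naive exhaustive scans) and never call the functions they check.

## ---- rho/sigma by per-tip path walking ---------------------------------

oracle_rho_sigma <- function(g) {
  edges <- g$edges
  parent_of <- stats::setNames(edges$parent, edges$child)
  m_of <- stats::setNames(edges$m, edges$child)
  path_len <- function(tip) {
    tot <- 0; cur <- tip
    while (cur != g$root) {
      tot <- tot + m_of[[cur]]
      cur <- parent_of[[cur]]
    }
    tot
  }
  n <- sum(g$multiplicity)
  rho <- sum(vapply(g$tips, function(t) g$multiplicity[[t]] * path_len(t),
                    numeric(1))) / n
  ## sigma: n_l for edge e = number of sampled lineages whose root path uses e
  tips_through <- function(child) {
    sum(vapply(g$tips, function(t) {
      cur <- t
      while (cur != g$root) {
        if (cur == child) return(g$multiplicity[[t]])
        cur <- parent_of[[cur]]
      }
      0L
    }, numeric(1)))
  }
  nl <- vapply(edges$child, tips_through, numeric(1))
  sigma <- sqrt(sum(nl^2 * edges$m)) / n
  list(rho = rho, sigma = sigma)
}

## ---- brute-force median-joining oracle ---------------------------------

okey <- function(states) apply(states, 1L, paste, collapse = "\r")

## full median closure by exhaustive triple scanning (binary states only:
## three binary values always have a majority, so no quasi-median ties)
oracle_closure <- function(states) {
  stopifnot(all(states %in% c("0", "1")))
  M <- matrix(as.integer(states), nrow = nrow(states))
  repeat {
    n <- nrow(M)
    if (n < 3L) break
    tri <- utils::combn(n, 3L)
    med <- (M[tri[1, ], , drop = FALSE] + M[tri[2, ], , drop = FALSE] +
              M[tri[3, ], , drop = FALSE] >= 2L) * 1L
    allkey <- apply(rbind(M, med), 1L, paste, collapse = "")
    keep <- !duplicated(allkey)
    keep[seq_len(n)] <- TRUE
    if (sum(keep) == n) break
    M <- rbind(M, med)[keep, , drop = FALSE]
  }
  out <- matrix(as.character(M), nrow = nrow(M))
  colnames(out) <- colnames(states)
  out
}

oracle_dist <- function(states, w) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(w[states[i, ] != states[j, ]])
  d
}

## epsilon-relaxed MSN via igraph connectivity
oracle_msn <- function(states, w, epsilon = 0) {
  n <- nrow(states)
  if (n < 2) return(cbind(from = integer(), to = integer()))
  d <- oracle_dist(states, w)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  repeat {
    memb <- igraph::components(g)$membership
    if (max(memb) == 1 && igraph::components(g)$no == 1) break
    cross <- which(outer(memb, memb, "!=") & upper.tri(d), arr.ind = TRUE)
    if (!nrow(cross)) break
    dc <- d[cross]
    sigma <- min(dc)
    take <- cross[dc <= sigma + epsilon, , drop = FALSE]
    g <- igraph::add_edges(g, t(take))
  }
  el <- igraph::as_edgelist(g)
  storage.mode(el) <- "integer"
  el
}

## remove unobserved degree<=2 nodes on no observed-pair geodesic, to a
## fixed point, rebuilding the MSN each round
oracle_prune <- function(states, observed, w, epsilon = 0) {
  repeat {
    el <- oracle_msn(states, w, epsilon)
    deg <- tabulate(c(el), nbins = nrow(states))
    d <- oracle_dist(states, w)
    obs <- which(observed)
    drop <- rep(FALSE, nrow(states))
    for (x in which(!observed)) {
      if (deg[x] > 2) next
      geo <- FALSE
      if (length(obs) >= 2) {
        prs <- utils::combn(obs, 2)
        for (cc in seq_len(ncol(prs))) {
          a <- prs[1, cc]; b <- prs[2, cc]
          if (abs(d[a, x] + d[x, b] - d[a, b]) < 1e-9) { geo <- TRUE; break }
        }
      }
      if (!geo) drop[x] <- TRUE
    }
    if (!any(drop)) return(list(states = states, observed = observed, links = el))
    states <- states[!drop, , drop = FALSE]
    observed <- observed[!drop]
  }
}

## full oracle: closure + MSN + pruning; returns canonical node-key set and
## link set (unordered pairs of node keys)
oracle_median_network <- function(states, weights = NULL, epsilon = 0) {
  w <- stats::setNames(rep(10, ncol(states)), colnames(states))
  if (!is.null(weights)) w[names(weights)] <- weights
  observed <- rep(TRUE, nrow(states))
  cl <- oracle_closure(states)
  observed <- c(observed, rep(FALSE, nrow(cl) - nrow(states)))
  res <- oracle_prune(cl, observed, w, epsilon)
  keys <- unname(okey(res$states))
  links <- if (nrow(res$links)) {
    unname(apply(res$links, 1L, function(e)
      paste(sort(c(keys[e[1]], keys[e[2]])), collapse = "|")))
  } else character()
  list(nodes = sort(keys), links = sort(links))
}

## canonical node/link key sets of an mt_network, for oracle comparison
network_keysets <- function(net) {
  st <- net$haplotypes$states
  keys <- apply(st, 1L, paste, collapse = "\r")
  names(keys) <- rownames(st)
  links <- if (nrow(net$links)) {
    vapply(seq_len(nrow(net$links)), function(r)
      paste(sort(c(keys[[net$links$from[r]]], keys[[net$links$to[r]]])),
            collapse = "|"), character(1))
  } else character()
  list(nodes = sort(unname(keys)), links = sort(unname(links)))
}

## random binary haplotype instance for network fuzzing; n_hap is capped at
## the number of distinct binary vectors so rejection sampling terminates
random_binary_instance <- function(n_hap, n_sites) {
  n_hap <- min(n_hap, 2^n_sites)
  repeat {
    st <- matrix(sample(c("0", "1"), n_hap * n_sites, replace = TRUE),
                 nrow = n_hap)
    if (!anyDuplicated(apply(st, 1, paste, collapse = ""))) break
  }
  colnames(st) <- as.character(seq_len(n_sites) + 16100L)
  rownames(st) <- paste0("H", seq_len(n_hap))
  st
}

## wrap a raw state matrix as mt_haplotypes (observed, count 1 each)
as_haplotypes <- function(states) {
  ids <- rownames(states)
  structure(list(states = states,
                 count = stats::setNames(rep(1L, nrow(states)), ids),
                 observed = stats::setNames(rep(TRUE, nrow(states)), ids),
                 regions = stats::setNames(rep(list(c(sim = 1L)), nrow(states)),
                                           ids)),
            class = "mt_haplotypes")
}
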