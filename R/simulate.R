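## Seeded simulators: star and coalescent genealogies with Poisson mutation
## counts, and multi-population haplogroup surveys with known ground truth.
## All randomness flows through the single seed in the configuration, so a
## configuration fully determines the dataset.

#' Simulation configuration
#'
#' @param n_tips number of sampled lineages (>= 1).
#' @param tree_shape \code{"star"} or \code{"coalescent"}.
#' @param tmrca_years for a star genealogy, the true age of the common
#'   ancestor; for a coalescent genealogy, the time scale (the expected
#'   pairwise coalescence time in years).
#' @param rate_per_year per-lineage mutation rate per year. The default is
#'   the HVS-I transition clock rate, 1/18845.
#' @param ts_tv_ratio transition:transversion odds for simulated mutations;
#'   the default \code{Inf} simulates pure transitions, the regime the HVS-I
#'   transition clock counts.
#' @param position_pool positions from which mutation sites are drawn
#'   (default the HVS-I clock window 16090-16365).
#' @param on_pool_exhausted \code{"resample"} (redraw the Poisson count until
#'   it fits the pool) or \code{"error"}.
#' @param seed integer seed; fully determines the simulated dataset.
#' @return an object of class \code{mt_simconfig}.
#' @export
sim_config <- function(n_tips = 50L, tree_shape = c("star", "coalescent"),
                       tmrca_years = 20000, rate_per_year = 1 / 18845,
                       ts_tv_ratio = Inf, position_pool = 16090:16365,
                       on_pool_exhausted = c("resample", "error"),
                       seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  on_pool_exhausted <- match.arg(on_pool_exhausted)
  stopifnot(n_tips >= 1L, tmrca_years > 0, rate_per_year >= 0,
            ts_tv_ratio > 0, length(position_pool) >= 1L)
  structure(list(n_tips = as.integer(n_tips), tree_shape = tree_shape,
                 tmrca_years = tmrca_years, rate_per_year = rate_per_year,
                 ts_tv_ratio = ts_tv_ratio,
                 position_pool = as.integer(position_pool),
                 on_pool_exhausted = on_pool_exhausted,
                 seed = as.integer(seed)),
            class = "mt_simconfig")
}

## draw a Poisson mutation count that fits the pool
draw_count <- function(lambda, pool_size, policy) {
  k <- stats::rpois(1L, lambda)
  if (k <= pool_size) return(k)
  if (policy == "error")
    stop("position pool (", pool_size, ") smaller than drawn mutation count ", k)
  repeat {
    k <- stats::rpois(1L, lambda)
    if (k <= pool_size) return(k)
  }
}

## token for a mutation at pos: transition = bare position, transversion =
## position + random base suffix
mutation_tokens <- function(positions, ts_tv_ratio) {
  if (!length(positions)) return(character())
  p_ts <- if (is.infinite(ts_tv_ratio)) 1 else ts_tv_ratio / (1 + ts_tv_ratio)
  is_ts <- stats::runif(length(positions)) < p_ts
  suffix <- ifelse(is_ts, "",
                   sample(c("A", "C", "G", "T"), length(positions), replace = TRUE))
  paste0(positions, suffix)
}

#' Simulate a star genealogy with Poisson mutations
#'
#' Each of \code{n_tips} lineages descends directly from the root and
#' receives \code{K ~ Poisson(tmrca_years * rate_per_year)} mutations at
#' positions drawn uniformly without replacement (per lineage) from the
#' position pool; transitions vs transversions follow \code{ts_tv_ratio}.
#' The emitted profiles are exactly the per-branch mutation sets, so the
#' dataset carries its own ground truth.
#'
#' @param cfg an \code{mt_simconfig} with \code{tree_shape = "star"}.
#' @return an object of class \code{mt_simdata}: \code{genealogy},
#'   \code{profiles}, \code{true_labels} (NULL here) and \code{truth}
#'   (\code{tmrca_years}, per-branch counts, expected rho).
#' @export
simulate_star_genealogy <- function(cfg) {
  stopifnot(inherits(cfg, "mt_simconfig"), cfg$tree_shape == "star")
  with_seed(cfg$seed, {
    lambda <- cfg$tmrca_years * cfg$rate_per_year
    ids <- sprintf("S%03d", seq_len(cfg$n_tips))
    muts <- vector("list", cfg$n_tips)
    for (i in seq_len(cfg$n_tips)) {
      k <- draw_count(lambda, length(cfg$position_pool), cfg$on_pool_exhausted)
      pos <- sort(sample(cfg$position_pool, k, replace = FALSE))
      muts[[i]] <- mutation_tokens(pos, cfg$ts_tv_ratio)
    }
    edges <- data.frame(parent = "root", child = ids, stringsAsFactors = FALSE)
    edges$mutations <- muts
    g <- genealogy(edges, root = "root")
    profiles <- lapply(seq_len(cfg$n_tips), function(i)
      mt_profile(ids[i], muts[[i]], population = "sim", region = "sim"))
    structure(list(genealogy = g, profiles = profiles, true_labels = NULL,
                   truth = list(tmrca_years = cfg$tmrca_years,
                                branch_counts = stats::setNames(lengths(muts), ids),
                                expected_rho = lambda),
                   config = cfg),
              class = "mt_simdata")
  })
}

#' Simulate a neutral coalescent genealogy with Poisson mutations
#'
#' Standard neutral coalescent: with k active lineages the waiting time to
#' the next coalescence is exponential with rate \code{choose(k, 2) /
#' tmrca_years} (so \code{tmrca_years} is the expected pairwise coalescence
#' time; for \code{n_tips = 2} the expected TMRCA equals it). Mutations are
#' Poisson on branch durations; sites are drawn without replacement across
#' the whole tree (infinite-sites behaviour), so tip profiles reconstruct
#' exactly by walking root-to-tip.
#'
#' @param cfg an \code{mt_simconfig} with \code{tree_shape = "coalescent"}.
#' @return an \code{mt_simdata}; \code{truth$tmrca_years} holds the realized
#'   TMRCA.
#' @export
simulate_coalescent_genealogy <- function(cfg) {
  stopifnot(inherits(cfg, "mt_simconfig"), cfg$tree_shape == "coalescent")
  with_seed(cfg$seed, {
    n <- cfg$n_tips
    ids <- sprintf("S%03d", seq_len(n))
    active <- ids
    height <- stats::setNames(rep(0, n), ids)   # node ages (years above tips)
    parent <- character(); child <- character(); duration <- numeric()
    t_now <- 0
    inode <- 0L
    while (length(active) > 1L) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1L, rate = choose(k, 2) / cfg$tmrca_years)
      pick <- sample(seq_len(k), 2L)
      inode <- inode + 1L
      anc <- paste0("A", inode)
      for (ch in active[pick]) {
        parent <- c(parent, anc); child <- c(child, ch)
        duration <- c(duration, t_now - height[[ch]])
      }
      height[anc] <- t_now
      active <- c(active[-pick], anc)
    }
    root <- if (n == 1L) ids else active
    edges <- data.frame(parent = parent, child = child, stringsAsFactors = FALSE)

    pool <- sample(cfg$position_pool)          # shuffled, consumed left to right
    used <- 0L
    muts <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      k <- draw_count(duration[e] * cfg$rate_per_year, length(pool) - used,
                      cfg$on_pool_exhausted)
      pos <- if (k > 0L) sort(pool[(used + 1L):(used + k)]) else integer()
      used <- used + k
      muts[[e]] <- mutation_tokens(pos, cfg$ts_tv_ratio)
    }
    edges$mutations <- muts

    if (n == 1L) {
      g <- genealogy(data.frame(parent = "root", child = ids,
                                mutations = I(list(character())),
                                stringsAsFactors = FALSE), root = "root")
      profiles <- list(mt_profile(ids, character(), population = "sim",
                                  region = "sim"))
      tmrca <- 0
    } else {
      g <- genealogy(edges, root = root)
      path_tokens <- function(tip) {
        toks <- character(); cur <- tip
        while (cur != root) {
          e <- which(edges$child == cur)
          toks <- c(toks, edges$mutations[[e]])
          cur <- edges$parent[e]
        }
        toks
      }
      profiles <- lapply(ids, function(id)
        mt_profile(id, path_tokens(id), population = "sim", region = "sim"))
      tmrca <- t_now
    }
    structure(list(genealogy = g, profiles = profiles, true_labels = NULL,
                   truth = list(tmrca_years = tmrca,
                                branch_counts = stats::setNames(lengths(muts),
                                                                edges$child)),
                   config = cfg),
              class = "mt_simdata")
  })
}

#' @export
print.mt_simdata <- function(x, ...) {
  cat("<mt_simdata>", length(x$profiles), "profiles,",
      if (!is.null(x$genealogy)) paste(sum(x$genealogy$edges$m), "mutations")
      else "", "\n")
  invisible(x)
}

#' Simulate a multi-population haplogroup survey
#'
#' Draws, for every region, a multinomial sample across the supplied
#' haplogroup frequencies (the remainder being background mtDNAs that never
#' satisfy the candidate screen). A carrier's profile is the cumulative
#' defining motif of its haplogroup plus optional private mutations; with
#' homoplasy off (the default) private and background mutations avoid every
#' definer and screen-diagnostic position, so motif-based assignment can
#' recover the generating label exactly.
#'
#' Carriers of a node whose cumulative motif does not by itself satisfy the
#' screen (e.g. basal members of the focal clade, known only from their
#' control-region motif) are completed with the tokens in
#' \code{motif_complete}, mirroring survey samples that are screen-positive
#' but carry no subclade information.
#'
#' @param freq_table named list: region -> named numeric vector of haplogroup
#'   frequencies in [0, 1] with sum <= 1.
#' @param sizes named integer vector: region -> number of sampled subjects.
#' @param tree an \code{mt_hgtree}.
#' @param seed integer seed.
#' @param private_lambda Poisson mean of private mutations per carrier.
#' @param background_lambda Poisson mean of variants per background profile.
#' @param clade_motif named list: node -> tokens carried by every member of
#'   that node's clade (the node and all descendants). The default gives all
#'   M9a'b members the shared control-region sites 153, 16223 and 16362,
#'   which together with M9a's defining 16234 complete the screen motif on
#'   the M9a side (M9b members are screen-positive through coding site 4491).
#' @param motif_complete named list: node -> extra tokens emitted with
#'   carriers assigned exactly to that node (default gives basal M9a'b
#'   members the 16234 transition, so they present the full control-region
#'   motif but no subclade information, like literature HVS-I-only samples).
#' @param homoplasy allow private/background mutations to hit definer and
#'   screen positions (off by default).
#' @return an \code{mt_simdata} with \code{profiles} and \code{true_labels}
#'   (named by sample id; background samples are labelled \code{NA}).
#' @export
simulate_population_survey <- function(freq_table, sizes, tree, seed = 1L,
                                       private_lambda = 1,
                                       background_lambda = 2,
                                       clade_motif = list("M9a'b" = c("153", "16223", "16362")),
                                       motif_complete = list("M9a'b" = "16234"),
                                       homoplasy = FALSE) {
  stopifnot(inherits(tree, "mt_hgtree"))
  regions <- names(freq_table)
  if (is.null(regions) || !all(regions %in% names(sizes)))
    stop("freq_table and sizes must be named by the same regions")
  screen_sites <- c(16223L, 16234L, 16362L, 153L, 3394L, 4491L)
  definer_pos <- unique(unlist(lapply(tree$nodes, function(nm) {
    toks <- tree$definers[[nm]]
    if (length(toks)) parse_variant_token(sub("^@", "", toks))$position
    else integer()
  })))
  motif_pos <- unlist(lapply(c(clade_motif, motif_complete), function(tk)
    parse_variant_token(sub("^@", "", tk))$position))
  pool <- 16090:16365
  if (!homoplasy) pool <- setdiff(pool, c(definer_pos, screen_sites, motif_pos))

  with_seed(seed, {
    profiles <- list(); labels <- character()
    for (rg in regions) {
      fr <- freq_table[[rg]]
      if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-12)
        stop("frequencies for region '", rg, "' must be in [0,1] and sum <= 1")
      nrg <- as.integer(sizes[[rg]])
      counts <- as.vector(stats::rmultinom(1L, nrg, c(fr, 1 - sum(fr))))
      hgs <- c(names(fr), NA)
      idx <- 0L
      for (h in seq_along(hgs)) {
        for (j in seq_len(counts[h])) {
          idx <- idx + 1L
          id <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", rg), idx)
          if (is.na(hgs[h])) {                       # background, screen-negative
            k <- stats::rpois(1L, background_lambda)
            toks <- as.character(sort(sample(pool, min(k, length(pool)))))
          } else {
            motif <- cumulative_motif(tree, hgs[h])
            motif <- motif[!startsWith(motif, "@")]
            path <- tree_path(tree, hgs[h])
            shared <- unlist(clade_motif[names(clade_motif) %in% path],
                             use.names = FALSE)
            extra <- motif_complete[[hgs[h]]] %||% character()
            k <- stats::rpois(1L, private_lambda)
            priv <- as.character(sort(sample(pool, min(k, length(pool)))))
            toks <- unique(c(motif, shared, extra, priv))
          }
          profiles[[length(profiles) + 1L]] <-
            mt_profile(id, toks, population = rg, region = rg,
                       source = "study")
          labels[id] <- hgs[h]
        }
      }
    }
    structure(list(genealogy = NULL, profiles = profiles, true_labels = labels,
                   truth = NULL,
                   config = list(freq_table = freq_table, sizes = sizes,
                                 seed = seed)),
              class = "mt_simdata")
  })
}
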