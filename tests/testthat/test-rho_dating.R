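star_g <- function(n, k) {
  edges <- data.frame(parent = "root", child = paste0("t", seq_len(n)),
                      stringsAsFactors = FALSE)
  edges$m <- rep(k, n)
  genealogy(edges, root = "root")
}

test_that("rho and sigma have their closed forms on simple genealogies", {
  g <- star_g(4, 1)
  expect_equal(rho_statistic(g), 1.0)
  expect_equal(sigma_statistic(g), 0.5)

  # tips at path lengths 2, 2, 0: rho is their mean
  ed <- data.frame(parent = "root", child = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  ed$m <- c(2L, 2L, 0L)
  expect_equal(rho_statistic(genealogy(ed, root = "root")), 4 / 3)

  # a single sampled lineage with m mutations: rho = m, sigma = sqrt(m)
  for (m in c(0L, 1L, 4L, 9L)) {
    ed1 <- data.frame(parent = "root", child = "t1", stringsAsFactors = FALSE)
    ed1$m <- m
    g1 <- genealogy(ed1, root = "root")
    expect_equal(rho_statistic(g1), m)
    expect_equal(sigma_statistic(g1), sqrt(m))
  }

  # star with n tips, k mutations each: rho = k, sigma = sqrt(k/n)
  for (n in c(2, 5, 10)) for (k in c(1, 3)) {
    g <- star_g(n, k)
    expect_equal(rho_statistic(g), k)
    expect_equal(sigma_statistic(g), sqrt(k / n))
  }
})

test_that("rho and sigma match the independent path-walk oracle", {
  set.seed(301)
  for (i in 1:200) {
    g <- random_genealogy(sample(4:12, 1))
    orc <- oracle_rho_sigma(g)
    expect_equal(rho_statistic(g), orc$rho)
    expect_equal(sigma_statistic(g), orc$sigma)
  }
})

test_that("rho and sigma are invariant to relabeling and tip expansion", {
  set.seed(302)
  for (i in 1:20) {
    g <- random_genealogy(8)
    # relabel all nodes
    map <- stats::setNames(paste0("x", seq_along(unique(c(g$edges$parent, g$edges$child)))),
                           unique(c(g$edges$parent, g$edges$child)))
    ed <- data.frame(parent = unname(map[g$edges$parent]),
                     child = unname(map[g$edges$child]),
                     stringsAsFactors = FALSE)
    ed$m <- g$edges$m
    g2 <- genealogy(ed, root = unname(map[g$root]),
                    multiplicity = stats::setNames(g$multiplicity,
                                                   unname(map[g$tips])))
    expect_equal(rho_statistic(g2), rho_statistic(g))
    expect_equal(sigma_statistic(g2), sigma_statistic(g))

    # split one multi-tip into identical unit tips via a zero-length fork
    tip <- g$tips[which.max(g$multiplicity)]
    cc <- g$multiplicity[[tip]]
    if (cc > 1) {
      ed3 <- g$edges[, c("parent", "child")]
      ed3$m <- g$edges$m
      add <- data.frame(parent = tip, child = paste0(tip, "_", seq_len(cc)),
                        stringsAsFactors = FALSE)
      add$m <- 0L
      ed3 <- rbind(ed3, add)
      mult <- g$multiplicity[setdiff(g$tips, tip)]
      g3 <- genealogy(ed3, root = g$root, multiplicity = mult)
      expect_equal(rho_statistic(g3), rho_statistic(g))
      expect_equal(sigma_statistic(g3), sigma_statistic(g))
    }

    # adding a mutation to any link cannot decrease rho
    j <- sample(nrow(g$edges), 1)
    ed4 <- g$edges[, c("parent", "child")]
    ed4$m <- g$edges$m
    ed4$m[j] <- ed4$m[j] + 1L
    g4 <- genealogy(ed4, root = g$root, multiplicity = g$multiplicity)
    expect_gte(rho_statistic(g4), rho_statistic(g))
  }
})

test_that("misrooted or non-tree input is rejected", {
  ed <- data.frame(parent = c("r", "r", "a"), child = c("a", "b", "b"))
  expect_error(genealogy(ed, root = "r"), "two parents")
  ed <- data.frame(parent = c("r", "q"), child = c("a", "b"))
  expect_error(genealogy(ed, root = "r"), "root")
  ed <- data.frame(parent = "r", child = "a")
  expect_error(genealogy(ed, root = "a"), "misrooted|unrooted")
  expect_error(genealogy(ed, root = "r", multiplicity = c(a = 0L)), ">= 1")
})

test_that("clock conversion is exact for linear clocks and delegates for custom", {
  a <- estimate_age(1.20, 0.46, hvsi_clock(), n = 50)
  expect_equal(a$T_years, 1.20 * 18845)
  expect_equal(a$deltaT_years, 0.46 * 18845)
  expect_equal(unname(age_ky(a)), c(22.6, 8.7))

  expect_equal(estimate_age(0, 0, hvsi_clock())$T_years, 0)

  set.seed(303)
  for (i in 1:50) {
    rho <- runif(1, 0, 12); sigma <- runif(1, 0, 3); rate <- runif(1, 100, 30000)
    a <- estimate_age(rho, sigma, linear_clock(rate))
    expect_equal(a$T_years / rate, rho, tolerance = 1e-12)
    expect_equal(a$deltaT_years / rate, sigma, tolerance = 1e-12)
  }

  conv <- function(r) 2500 * r + 100 * r^2   # a user-supplied calibration
  a <- estimate_age(2, 0.5, custom_clock(conv))
  expect_equal(a$T_years, conv(2))
  expect_equal(a$deltaT_years, conv(2.5) - conv(2))

  expect_error(linear_clock(0), "positive")
  expect_error(linear_clock(-5), "positive")
})

test_that("display rounding is half-up at one decimal of a kiloyear", {
  expect_equal(round_half_up(5.6535, 1), 5.7)
  expect_equal(round_half_up(22.6145, 1), 22.6)
  expect_equal(round_half_up(0.05, 1), 0.1)
})

test_that("clade dating applies the clock's mutation filter per link", {
  mk <- function(tokens) {
    ed <- data.frame(parent = "root", child = "t1", stringsAsFactors = FALSE)
    ed$mutations <- list(tokens)
    genealogy(ed, root = "root")
  }
  # heteroplasmies, 16519, C-stretch indels and 11778 never contribute
  expect_equal(date_clade(mk("16189Y"), hvsi_clock())$rho, 0)
  expect_equal(date_clade(mk("16519"), hvsi_clock())$rho, 0)
  expect_equal(date_clade(mk("309+C"), linear_clock(1000))$rho, 0)
  expect_equal(date_clade(mk("11778"), linear_clock(1000))$rho, 0)
  # transversions and coding transitions are outside the HVS-I transition clock
  expect_equal(date_clade(mk(c("16265C", "3394")), hvsi_clock())$rho, 0)
  # accepted HVS-I transitions count, including declared back mutations
  expect_equal(date_clade(mk(c("16234", "@16291", "16189Y", "16519")),
                          hvsi_clock())$rho, 2)
  # the excluded-site list is configurable
  expect_equal(date_clade(mk("16111"), hvsi_clock(), exclude_sites = 16111)$rho, 0)

  # synonymous-only clocks need annotation inputs
  expect_error(date_clade(mk("3394"), linear_clock(3500, filter = "synonymous_only")),
               "gene table")
  ref <- toy_ref(); genes <- toy_genes()
  syn_clock <- linear_clock(3500, filter = "synonymous_only")
  g <- mk(c("3C", "1C"))          # one synonymous, one nonsynonymous change
  a <- date_clade(g, syn_clock, genes = genes, ref = ref)
  expect_equal(a$rho, 1)
  expect_equal(a$T_years, 3500)
})

test_that("star genealogies built from profiles date like their counts", {
  ps <- list(mp(c("16223", "16234", "16093"), id = "a"),
             mp(c("16223", "16234"), id = "b"),
             mp(c("16223"), id = "c"))
  g <- genealogy_from_profiles(ps, root_tokens = c("16223", "16234"))
  # path lengths to the ancestral motif: 1, 0, 1 (loss of 16234)
  expect_equal(rho_statistic(g), 2 / 3)
  a <- date_clade(g, hvsi_clock(), exclude_sites = integer())
  expect_equal(a$rho, 2 / 3)
  expect_equal(a$n, 3L)

  # condensed mode merges identical tips into multiplicities
  ps2 <- c(ps, list(mp(c("16223", "16234"), id = "d")))
  g2 <- genealogy_from_profiles(ps2, root_tokens = c("16223", "16234"),
                                condense_tips = TRUE)
  expect_equal(sum(g2$multiplicity), 4)
  expect_equal(length(g2$tips), 3L)
  expect_equal(rho_statistic(g2), 2 / 4)
})
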