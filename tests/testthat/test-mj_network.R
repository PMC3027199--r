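test_that("condensation merges identical haplotypes deterministically", {
  ps <- list(mp(c("16223", "16234"), id = "a", region = "Tibet"),
             mp(c("16223", "16234"), id = "b", region = "Nepal"),
             mp("16223", id = "c", region = "Tibet"))
  h <- condense(ps)
  expect_equal(nrow(h$states), 2L)
  big <- names(h$count)[h$count == 2L]
  expect_equal(h$regions[[big]], c(Nepal = 1L, Tibet = 1L))

  # n distinct profiles stay n haplotypes
  ps2 <- lapply(1:4, function(i) mp(as.character(16100 + i), id = paste0("s", i)))
  expect_equal(nrow(condense(ps2)$states), 4L)

  # degenerate: no positions selected collapses everything onto one node
  h0 <- condense(ps2, positions = integer())
  expect_equal(nrow(h0$states), 1L)
  expect_equal(unname(h0$count), 4L)
})

test_that("weighted distance sums weights over differing positions", {
  a <- c("16101" = "1", "16102" = "0", "16103" = "0")
  b <- c("16101" = "1", "16102" = "0", "16103" = "0")
  expect_equal(weighted_distance(a, b), 0)
  b["16103"] <- "1"
  expect_equal(weighted_distance(a, b), 10)
  b["16102"] <- "1"
  expect_equal(weighted_distance(a, b, weights = c("16102" = 10, "16103" = 20)), 30)
  expect_equal(weighted_distance(a, b), weighted_distance(b, a))
})

test_that("minimum spanning networks keep all equally short alternatives", {
  # two haplotypes: one link
  st <- random_binary_instance(2, 3)
  net <- minimum_spanning_network(as_haplotypes(st))
  expect_equal(nrow(net$links), 1L)

  # three pairwise-equidistant haplotypes: the whole triangle survives
  st <- matrix(c("1", "0", "0",
                 "0", "1", "0",
                 "0", "0", "1"), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("H", 1:3), c("16101", "16102", "16103")))
  net <- minimum_spanning_network(as_haplotypes(st))
  expect_equal(nrow(net$links), 3L)

  # collinear A-B-C: only the two short links appear
  st <- matrix(c("0", "0",
                 "1", "0",
                 "1", "1"), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("H", 1:3), c("16101", "16102")))
  net <- minimum_spanning_network(as_haplotypes(st))
  expect_equal(nrow(net$links), 2L)
  expect_setequal(paste(net$links$from, net$links$to),
                  c("H1 H2", "H2 H3"))
})

test_that("median joining infers the ancestral intermediate of a fork", {
  # {}, {a,b}, {a,c}: exactly one median, the vector {a}
  ps <- list(mp(character(), id = "h1"),
             mp(c("16100", "16200"), id = "h2"),
             mp(c("16100", "16300"), id = "h3"))
  net <- median_joining(condense(ps))
  h <- net$haplotypes
  expect_equal(sum(!h$observed), 1L)
  expect_equal(unname(h$states["mv1", ]), c("1", "0", "0"))
  expect_equal(unname(h$count["mv1"]), 0L)
  expect_equal(nrow(net$links), 3L)
  expect_setequal(net$links$to, c("mv1"))
  expect_setequal(net$links$labels, c("16100", "16200", "16300"))

  # two haplotypes: no medians possible
  net2 <- median_joining(condense(ps[1:2]))
  expect_equal(sum(!net2$haplotypes$observed), 0L)
  expect_equal(nrow(net2$links), 1L)

  # all identical: a single node and no links
  net3 <- median_joining(condense(list(mp("16100", id = "x"),
                                       mp("16100", id = "y"))))
  expect_equal(nrow(net3$haplotypes$states), 1L)
  expect_equal(nrow(net3$links), 0L)
})

test_that("median-joining networks satisfy their structural invariants", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:40) {
    st <- random_binary_instance(sample(3:5, 1), sample(3:6, 1))
    net <- median_joining(as_haplotypes(st))
    h <- net$haplotypes
    n <- nrow(h$states)

    # connected, and the links contain an MST of the final node set
    g <- igraph::graph_from_data_frame(net$links[c("from", "to")],
                                       directed = FALSE,
                                       vertices = rownames(h$states))
    expect_true(igraph::is_connected(g))
    w <- net$weights
    dfull <- oracle_dist(h$states, w)
    dimnames(dfull) <- list(rownames(h$states), rownames(h$states))
    gc <- igraph::graph_from_adjacency_matrix(dfull, mode = "undirected",
                                              weighted = TRUE)
    mst_w <- sum(igraph::E(igraph::mst(gc))$weight)
    gl <- igraph::graph_from_data_frame(net$links[c("from", "to")],
                                        directed = FALSE,
                                        vertices = rownames(h$states))
    igraph::E(gl)$weight <- net$links$length
    expect_equal(sum(igraph::E(igraph::mst(gl))$weight), mst_w)

    # every degree-<=2 median sits on a shortest connection between
    # observed haplotypes (the retention rule)
    deg <- table(factor(c(net$links$from, net$links$to),
                        levels = rownames(h$states)))
    obs_ids <- rownames(h$states)[h$observed]
    for (mid in rownames(h$states)[!h$observed]) {
      if (deg[[mid]] > 2) next
      on_geo <- FALSE
      for (a in obs_ids) for (b in obs_ids) {
        if (a >= b) next
        if (abs(dfull[mid, a] + dfull[mid, b] - dfull[a, b]) < 1e-9) {
          on_geo <- TRUE; break
        }
      }
      expect_true(on_geo, info = mid)
    }

    # every retained median is a per-position median of some node triple
    cl_keys <- apply(oracle_closure(st), 1, paste, collapse = "\r")
    med_keys <- apply(h$states[!h$observed, , drop = FALSE], 1, paste,
                      collapse = "\r")
    expect_true(all(med_keys %in% cl_keys))
  }
})

test_that("input order never changes the network", {
  set.seed(7)
  ps <- lapply(1:6, function(i)
    mp(sample(c("16101", "16150", "16200", "16250"), sample(3, 1)),
       id = paste0("s", i), region = sample(c("A", "B"), 1)))
  ps[[7]] <- mp(c("16101", "16150"), id = "s7", region = "A")
  net1 <- median_joining(condense(ps))
  for (rep in 1:5) {
    net2 <- median_joining(condense(sample(ps)))
    expect_identical(net1$haplotypes$states, net2$haplotypes$states)
    expect_identical(net1$links, net2$links)
    expect_identical(net1$haplotypes$count, net2$haplotypes$count)
  }
})

test_that("networks export to text and re-import exactly", {
  ps <- list(mp(character(), id = "h1", region = "Tibet"),
             mp(c("16100", "16200"), id = "h2", region = "Nepal"),
             mp(c("16100", "16300"), id = "h3", region = "Tibet"))
  net <- median_joining(condense(ps))
  f <- tempfile(fileext = ".txt")
  export_network(net, f)
  back <- read_network(f)
  expect_identical(back$haplotypes$states, net$haplotypes$states)
  expect_identical(back$haplotypes$count, net$haplotypes$count)
  expect_identical(back$haplotypes$observed, net$haplotypes$observed)
  expect_identical(back$haplotypes$regions, net$haplotypes$regions)
  expect_equal(back$links, net$links)
  expect_equal(back$epsilon, net$epsilon)
  expect_equal(back$weights, net$weights)

  # the median row is flagged unobserved in the file
  lines <- readLines(f)
  mvline <- grep("^mv1\t", lines, value = TRUE)
  expect_equal(strsplit(mvline, "\t")[[1]][3], "0")

  # single-node network: one node row, no edge rows
  net1 <- median_joining(condense(list(mp("16100", id = "x"))))
  export_network(net1, f)
  back1 <- read_network(f)
  expect_equal(nrow(back1$haplotypes$states), 1L)
  expect_equal(nrow(back1$links), 0L)
})
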