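## Shared fixtures, built in code at test time.

## profile shortcut
mp <- function(tokens, id = "s1", pop = NA, region = NA, source = "study",
               ref = NULL) {
  mt_profile(id, tokens, population = pop, region = region, source = source,
             ref = ref)
}

## toy reference and gene table for codon-level effect tests:
## pos 1-6 a protein record (codons GCT GCT = Ala Ala), pos 7-10 a tRNA,
## pos 11-14 a control feature
toy_ref <- function() reference_genome("toy", "GCTGCTTAAGGCCA")

toy_genes <- function() {
  gene_table(data.frame(
    name = c("P1", "T1", "CR"),
    start = c(1L, 7L, 11L),
    end = c(6L, 10L, 14L),
    type = c("protein", "tRNA", "control"),
    strand = "+",
    phase = 0L))
}

## random rooted genealogy by sequential attachment; every edge carries a
## small mutation count, tips get random multiplicities
random_genealogy <- function(n_nodes = 8, max_m = 3) {
  stopifnot(n_nodes >= 2)
  nodes <- paste0("n", seq_len(n_nodes))
  parent <- character(n_nodes - 1)
  for (i in 2:n_nodes) parent[i - 1] <- nodes[sample(i - 1, 1)]
  edges <- data.frame(parent = parent, child = nodes[-1],
                      stringsAsFactors = FALSE)
  edges$m <- sample(0:max_m, n_nodes - 1, replace = TRUE)
  tips <- setdiff(nodes, edges$parent)
  mult <- stats::setNames(sample(1:3, length(tips), replace = TRUE), tips)
  genealogy(edges, root = "n1", multiplicity = mult)
}
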