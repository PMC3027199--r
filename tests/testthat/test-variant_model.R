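test_that("variant tokens parse into typed records", {
  v <- parse_variant_token(c("16234", "249d", "5899+C", "@16291", "16189Y"))
  expect_equal(v$position, c(16234L, 249L, 5899L, 16291L, 16189L))
  expect_equal(v$kind, c("transition", "deletion", "insertion", "transition",
                         "transition"))
  expect_equal(v$derived, c("", "", "C", "", "Y"))
  expect_equal(v$back, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(v$heteroplasmic, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # without a reference a base suffix is recorded as stated: a transversion
  expect_equal(parse_variant_token("16265C")$kind, "transversion")
  # with a reference the base is resolved against the reference class
  ref <- reference_genome("r", "ACGT")
  expect_equal(parse_variant_token("3A", ref)$kind, "transition")   # G -> A
  expect_equal(parse_variant_token("3C", ref)$kind, "transversion") # G -> C
})

test_that("malformed tokens raise errors naming the token", {
  expect_error(parse_variant_token("noDigits"), "noDigits")
  expect_error(parse_variant_token("16234X"), "16234X")
  expect_error(parse_variant_token("16234+"), "\\+")
  ref <- reference_genome("r", "ACGT")
  expect_error(parse_variant_token("5", ref), "out of range")
})

test_that("parse/format round-trips every grammar case", {
  cases <- c("16234", "16265C", "249d", "5899+C", "@16291", "16189Y",
             "16293R", "@249d", "152", "310+CT")
  expect_identical(format_variant(parse_variant_token(cases)), cases)

  set.seed(11)
  for (i in 1:200) {
    pos <- sample(16569L, 1)
    tok <- switch(sample(5, 1),
                  as.character(pos),
                  paste0(pos, sample(c("A", "C", "G", "T"), 1)),
                  paste0(pos, "d"),
                  paste0(pos, "+", paste(sample(c("A", "C", "G", "T"),
                                                sample(3, 1), replace = TRUE),
                                         collapse = "")),
                  paste0(pos, sample(c("R", "Y"), 1)))
    if (sample(c(TRUE, FALSE), 1)) tok <- paste0("@", tok)
    v <- parse_variant_token(tok)
    expect_identical(format_variant(v), tok)
    expect_identical(parse_variant_token(format_variant(v)), v)
  }
})

test_that("scoring an aligned sequence emits rCRS-relative variants", {
  ref <- reference_genome("r", "ACGT")
  expect_equal(format_variant(score_against_reference("ACAT", ref)), "3")
  expect_equal(format_variant(score_against_reference("AC-T", ref)), "3d")
  expect_equal(format_variant(score_against_reference("ACTGT", "AC-GT")), "2+T")

  # the reference against itself is the empty profile
  expect_equal(nrow(score_against_reference("ACGT", ref)), 0L)

  # a deletion run emits one deletion per reference base; a gap run in the
  # reference emits a single anchored multi-base insertion
  expect_equal(format_variant(score_against_reference("A--T", ref)),
               c("2d", "3d"))
  expect_equal(format_variant(score_against_reference("ACTTGT", "AC--GT")),
               "2+TT")

  # IUPAC R/Y compatible with the reference base scores a heteroplasmy
  v <- score_against_reference("AYGT", ref)
  expect_true(v$heteroplasmic)
  expect_equal(format_variant(v), "2Y")

  expect_error(score_against_reference("ACG", ref), "length")
  expect_error(score_against_reference("AC?T", ref), "column 3")
  expect_error(score_against_reference("ARGT", ref), "incompatible")
})

test_that("default mask drops 16519 and C-stretch length variants only", {
  expect_equal(format_variant(apply_mask(parse_variant_token(c("16519", "16234")))),
               "16234")
  # indels in the length regions go, point substitutions there stay
  expect_equal(format_variant(apply_mask(parse_variant_token(c("309+C", "16189")))),
               "16189")
  expect_equal(nrow(apply_mask(mt_variants())), 0L)

  # idempotent, never adds variants
  set.seed(5)
  for (i in 1:20) {
    v <- parse_variant_token(sample(c("16519", "309+C", "16189", "16182d",
                                      "73", "263", "16234", "310+CT"),
                                    sample(5, 1)))
    m1 <- apply_mask(v)
    expect_identical(apply_mask(m1), m1)
    expect_lte(nrow(m1), nrow(v))
    expect_true(all(format_variant(m1) %in% format_variant(v)))
  }
})

test_that("functional effects follow the vertebrate mitochondrial code", {
  ref <- toy_ref(); genes <- toy_genes()
  # GCT -> GCC at pos 3 stays Ala; GCT -> CCT at pos 1 is Ala -> Pro
  expect_equal(classify_functional_effect(parse_variant_token("3C", ref), genes, ref),
               "synonymous")
  expect_equal(classify_functional_effect(parse_variant_token("1C", ref), genes, ref),
               "nonsynonymous")
  expect_equal(classify_functional_effect(parse_variant_token("8A", ref), genes, ref),
               "tRNA")
  expect_equal(classify_functional_effect(parse_variant_token("12A", ref), genes, ref),
               "control")
  expect_equal(classify_functional_effect(parse_variant_token(c("3d", "5+C"), ref),
                                          genes, ref),
               c("indel", "indel"))

  # control feature spanning 16234 in a full-length synthetic reference
  big <- synthetic_reference()
  cr <- gene_table(data.frame(name = "CR", start = 16024L, end = 16569L,
                              type = "control", strand = "+", phase = 0L))
  expect_equal(classify_functional_effect(parse_variant_token("16234", big), cr, big),
               "control")
  # a position outside any record is intergenic
  expect_equal(classify_functional_effect(parse_variant_token("100", big), cr, big),
               "intergenic")

  # cross-check substitutions against Biostrings translation directly
  code <- Biostrings::getGeneticCode("2")
  for (tok in c("2A", "4T", "5G", "6A")) {
    v <- parse_variant_token(tok, ref)
    got <- classify_functional_effect(v, genes, ref)
    cod <- substring(ref$sequence, 3 * ((v$position - 1) %/% 3) + 1,
                     3 * ((v$position - 1) %/% 3) + 3)
    alt <- cod
    db <- if (v$derived == "") chartr("ACGT", "GTAC", substring(ref$sequence, v$position, v$position)) else v$derived
    substring(alt, (v$position - 1) %% 3 + 1, (v$position - 1) %% 3 + 1) <- db
    expect_equal(got, ifelse(code[[cod]] == code[[alt]], "synonymous",
                             "nonsynonymous"),
                 info = tok)
  }
})

test_that("HVS-I transition counting honours window, mask and flags", {
  expect_equal(count_hvsi_transitions(mp(c("16223", "16234", "16362", "153"))), 3)
  expect_equal(count_hvsi_transitions(mp("16519")), 0)
  expect_equal(count_hvsi_transitions(mp("16265C")), 0)          # transversion
  expect_equal(count_hvsi_transitions(mp(c("16189Y", "@16291"))), 0)  # het/back
  expect_equal(count_hvsi_transitions(mp("16189")), 1)  # point ts in C-stretch

  # order-invariant and bounded by the profile size
  set.seed(8)
  toks <- c("16093", "16223", "16234", "16362", "153", "16519", "16265C")
  for (i in 1:10) {
    sh <- sample(toks)
    expect_equal(count_hvsi_transitions(parse_variant_token(sh)),
                 count_hvsi_transitions(parse_variant_token(toks)))
    expect_lte(count_hvsi_transitions(parse_variant_token(sh)), length(toks))
  }
})

test_that("profile TSV round-trips", {
  ps <- list(mp(c("16223", "16234", "249d"), id = "a", pop = "P1", region = "Tibet"),
             mp("3394", id = "b", pop = "P2", region = "southern China",
                source = "literature"),
             mp(character(), id = "c"))
  f <- tempfile(fileext = ".tsv")
  write_profiles(ps, f, comments = "fixture")
  back <- read_profiles(f)
  expect_equal(length(back), 3L)
  for (i in seq_along(ps)) {
    expect_identical(back[[i]]$sample_id, ps[[i]]$sample_id)
    expect_identical(back[[i]]$variants, ps[[i]]$variants)
    expect_identical(back[[i]]$population, ps[[i]]$population)
    expect_identical(back[[i]]$source, ps[[i]]$source)
  }
})
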