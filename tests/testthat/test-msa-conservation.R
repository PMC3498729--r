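toy_alignment <- function() {
  subfamily_alignment(
    c(outgroup = "CKGT-A", s1a = "CKGNLA", s1b = "CKSNLA",
      s2a = "CKGNLA", s2b = "CRSNLV"),
    subfamily = "toy")
}

test_that("classify_column resolves the canonical category examples", {
  cases <- list(
    list(col = c(outgroup = "C", s1a = "C", s1b = "C", s2a = "C", s2b = "C"),
         cat = "conserved_cys", div = NA_character_),
    list(col = c(outgroup = "K", s1a = "K", s1b = "K", s2a = "K", s2b = "R"),
         cat = "single_gene_divergent", div = "s2b"),
    list(col = c(outgroup = "G", s1a = "G", s1b = "S", s2a = "G", s2b = "S"),
         cat = "paralogue_a_conserved", div = NA_character_),
    list(col = c(outgroup = "T", s1a = "N", s1b = "N", s2a = "N", s2b = "N"),
         cat = "vertebrate_only", div = NA_character_),
    list(col = c(outgroup = "-", s1a = "L", s1b = "L", s2a = "L", s2b = "L"),
         cat = "outgroup_gap", div = NA_character_),
    # mirror of the a-specific case
    list(col = c(outgroup = "G", s1a = "S", s1b = "G", s2a = "S", s2b = "G"),
         cat = "paralogue_b_conserved", div = NA_character_),
    # species-specific conservation is deliberately not a counted category
    list(col = c(outgroup = "G", s1a = "G", s1b = "G", s2a = "S", s2b = "S"),
         cat = "unclassified", div = NA_character_)
  )
  for (cs in cases) {
    got <- classify_column(cs$col)
    expect_identical(got$category, cs$cat, info = paste(cs$col, collapse = ""))
    expect_identical(got$divergent_role, cs$div)
  }
})

test_that("classify_column gap and cysteine priorities hold", {
  # outgroup gap wins even over an otherwise all-cysteine vertebrate column
  expect_identical(
    classify_column(c(outgroup = "-", s1a = "C", s1b = "C", s2a = "C", s2b = "C"))$category,
    "outgroup_gap")
  # vertebrate gap counts as a mismatch, never as a match
  expect_identical(
    classify_column(c(outgroup = "K", s1a = "K", s1b = "K", s2a = "K", s2b = "-"))$category,
    "single_gene_divergent")
  # a cysteine column with one divergence is not conserved_cys
  got <- classify_column(c(outgroup = "C", s1a = "C", s1b = "C", s2a = "C", s2b = "S"))
  expect_identical(got$category, "single_gene_divergent")
  expect_identical(got$divergent_role, "s2b")
})

test_that("classify_column rejects malformed input", {
  expect_error(classify_column(c(outgroup = "A", s1a = "A", s1b = "A", s2a = "A")),
               class = "paradiv_validation_error")
  expect_error(classify_column(c(outgroup = "A", s1a = "A", s1b = "A",
                                 s2a = "A", s2b = "Z")),
               class = "paradiv_validation_error")
})

test_that("similarity-group matching widens conservation calls", {
  p <- match_policy("groups")
  expect_true(residues_match("I", "L", p))
  expect_false(residues_match("I", "L", match_policy()))
  expect_false(residues_match("-", "-", p))
  # conservative substitution in one gene is invisible under groups matching
  col <- c(outgroup = "I", s1a = "I", s1b = "I", s2a = "I", s2b = "V")
  expect_identical(classify_column(col, p)$category, "fully_conserved")
  expect_identical(classify_column(col)$category, "single_gene_divergent")
})

test_that("profile_alignment reproduces the hand-enumerated toy profile", {
  prof <- profile_alignment(toy_alignment())
  expect_identical(prof$n_conserved_cys, 1L)
  expect_identical(prof$n_paralogue_a_specific, 1L)
  expect_identical(unname(prof$single_gene_divergence["s2b"]), 2L)
  expect_identical(sum(prof$single_gene_divergence), 2L)
  cc <- category_counts(prof)
  expect_identical(unname(cc["vertebrate_only"]), 1L)
  expect_identical(unname(cc["outgroup_gap"]), 1L)
  expect_identical(prof$columns$category,
                   c("conserved_cys", "single_gene_divergent",
                     "paralogue_a_conserved", "vertebrate_only",
                     "outgroup_gap", "single_gene_divergent"))
})

test_that("an alignment of identical rows is fully conserved", {
  row <- "MCDEKCW"
  aln <- subfamily_alignment(setNames(rep(row, 5), seq_roles()))
  prof <- profile_alignment(aln)
  expect_identical(prof$n_fully_conserved + prof$n_conserved_cys,
                   alignment_length(aln))
  expect_identical(sum(prof$single_gene_divergence), 0L)
  expect_equal(unname(prof$pairwise_similarity), rep(100, 4))
})

test_that("category counts always partition the columns", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(5:60, 1)
    mat <- replicate(L, random_column())
    aln <- subfamily_alignment(setNames(apply(mat, 1, paste, collapse = ""),
                                        seq_roles()))
    prof <- profile_alignment(aln)
    expect_identical(sum(category_counts(prof)), alignment_length(aln))
    expect_identical(unname(category_counts(prof)["single_gene_divergent"]),
                     sum(prof$single_gene_divergence))
  }
})

test_that("swapping species permutes divergence counts but fixes the summaries", {
  set.seed(202)
  for (i in 1:10) {
    mat <- replicate(40, random_column())
    rownames(mat) <- seq_roles()
    seqs <- apply(mat, 1, paste, collapse = "")
    aln <- subfamily_alignment(setNames(seqs, seq_roles()))
    swapped <- subfamily_alignment(setNames(
      seqs[c("outgroup", "s2a", "s2b", "s1a", "s1b")], seq_roles()))
    p1 <- profile_alignment(aln)
    p2 <- profile_alignment(swapped)
    expect_identical(p1$n_paralogue_a_specific, p2$n_paralogue_a_specific)
    expect_identical(p1$n_paralogue_b_specific, p2$n_paralogue_b_specific)
    expect_identical(p1$n_fully_conserved, p2$n_fully_conserved)
    expect_identical(p1$n_conserved_cys, p2$n_conserved_cys)
    expect_identical(unname(p1$single_gene_divergence[c("s1a", "s1b", "s2a", "s2b")]),
                     unname(p2$single_gene_divergence[c("s2a", "s2b", "s1a", "s1b")]))
  }
})

test_that("breaking a fully conserved column moves it into a divergence category", {
  aln <- subfamily_alignment(setNames(rep("KDEKW", 5), seq_roles()))
  base <- profile_alignment(aln)
  div_total <- function(p) {
    cc <- category_counts(p)
    sum(cc[c("single_gene_divergent", "paralogue_a_conserved",
             "paralogue_b_conserved", "vertebrate_only", "unclassified")])
  }
  for (role in setdiff(seq_roles(), "outgroup")) {
    res <- aln$residues
    res[role, 3] <- "A"
    mod <- subfamily_alignment(setNames(apply(res, 1, paste, collapse = ""),
                                        seq_roles()))
    prof <- profile_alignment(mod)
    expect_lt(prof$n_fully_conserved, base$n_fully_conserved)
    expect_gte(div_total(prof), div_total(base))
  }
})

test_that("pairwise similarity counts matches over mutually ungapped columns", {
  aln <- toy_alignment()
  # s1a: outgroup gapped at col 5 -> denominator 5; matches at 1,2,3,6
  expect_equal(pairwise_similarity(aln, "s1a"), 100 * 4 / 5)
  # identical row
  aln2 <- subfamily_alignment(setNames(rep("MKDE", 5), seq_roles()))
  expect_equal(pairwise_similarity(aln2, "s2b"), 100)
  # no match at any mutually ungapped column
  aln3 <- subfamily_alignment(c(outgroup = "KK", s1a = "EE", s1b = "KK",
                                s2a = "KK", s2b = "KK"))
  expect_equal(pairwise_similarity(aln3, "s1a"), 0)
  expect_error(pairwise_similarity(aln, "outgroup"),
               class = "paradiv_validation_error")
})

test_that("similarity is undefined without mutually ungapped columns", {
  aln <- subfamily_alignment(c(outgroup = "K-", s1a = "-K", s1b = "KK",
                               s2a = "KK", s2b = "KK"))
  expect_error(pairwise_similarity(aln, "s1a"),
               class = "paradiv_validation_error")
})

test_that("alignment construction enforces the five-role contract", {
  expect_error(subfamily_alignment(c(outgroup = "A", s1a = "A", s1b = "A",
                                     s2a = "A")),
               class = "paradiv_validation_error")
  expect_error(subfamily_alignment(c(outgroup = "AA", s1a = "A", s1b = "AA",
                                     s2a = "AA", s2b = "AA")),
               class = "paradiv_validation_error")
  expect_error(subfamily_alignment(c(outgroup = "A-", s1a = "A-", s1b = "A-",
                                     s2a = "A-", s2b = "A-")),
               class = "paradiv_validation_error")
})
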