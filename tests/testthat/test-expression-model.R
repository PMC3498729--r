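test_that("presence matrix marks any-stage detection and keeps input order", {
  terr <- data.frame(id = c("t1", "t2", "tail_bud"),
                     name = c("t1", "t2", "tail bud"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(
    gene = c("g1", "g2", "g2", "g3"),
    species = "chick", subfamily = "Wnt5",
    paralogue_tag = c("a", "b", "b", "a"),
    stage = c("HH20", "HH20", "HH23", "HH20"),
    territory_id = c("t1", "t1", "t2", "tail_bud"),
    domains = "d1", stringsAsFactors = FALSE)

  m <- build_presence_matrix(ann, terr, genes = c("g1", "g2", "g4"))
  expect_identical(dimnames(m), list(c("g1", "g2", "g4"), terr$id))
  expect_identical(unname(m["g1", ]), c(1L, 0L, 0L))
  expect_identical(unname(m["g2", ]), c(1L, 1L, 0L))
  expect_identical(unname(m["g4", ]), c(0L, 0L, 0L))

  # expression detected at a single stage is still presence
  single <- ann[ann$gene == "g3", ]
  m2 <- build_presence_matrix(single, terr)
  expect_identical(unname(m2["g3", ]), c(0L, 0L, 1L))

  # empty annotation set gives the all-zero matrix
  m3 <- build_presence_matrix(ann[0, ], terr, genes = "g1")
  expect_true(all(m3 == 0L))

  bad <- ann
  bad$territory_id[1] <- "nowhere"
  expect_error(build_presence_matrix(bad, terr), "nowhere",
               class = "paradiv_validation_error")
})

test_that("grade_pair implements the ordinal scoring rule", {
  expect_identical(grade_sets_via_pair(character(0), character(0)), "not_applicable")
  expect_identical(grade_sets_via_pair("dorsal_ectoderm", character(0)), "exclusive")
  expect_identical(grade_sets_via_pair("dorsal_ectoderm", "proximoventral_ectoderm"),
                   "diff_domain")
  expect_identical(grade_sets_via_pair(c("dorsal_ectoderm", "AER"), "dorsal_ectoderm"),
                   "minor_diff")
  expect_identical(grade_sets_via_pair("dorsal_ectoderm", "dorsal_ectoderm"),
                   "equal")
})

test_that("grade_pair axioms hold over all small domain-set pairs", {
  universe <- c("d1", "d2", "d3", "d4")
  subsets <- lapply(0:15, function(k) universe[bitwAnd(k, 2^(0:3)) > 0])
  for (d1 in subsets) {
    for (d2 in subsets) {
      g12 <- grade_sets_via_pair(d1, d2)
      g21 <- grade_sets_via_pair(d2, d1)
      expect_identical(g12, g21)
      expect_identical(g12 == "equal",
                       length(d1) > 0 && setequal(d1, d2))
      expect_identical(g12 == "exclusive",
                       xor(length(d1) == 0, length(d2) == 0))
      expect_identical(g12 == "not_applicable",
                       length(d1) == 0 && length(d2) == 0)
    }
  }
})

test_that("cross-species grading requires a stage map", {
  mk <- make_pair_annotations("d1", "d1", species = c("mouse", "chick"),
                              stages = list("TS15", "HH20"))
  expect_error(grade_pair(mk$annotations, "gene1", "gene2", "t1"),
               class = "paradiv_configuration_error")
  expect_identical(
    grade_pair(mk$annotations, "gene1", "gene2", "t1", default_stage_map()),
    "equal")
})

test_that("stage-identical patterns grade equal under every aggregation", {
  stages <- list(c("TS15", "TS17"), c("TS15", "TS17"))
  mk <- make_pair_annotations(c("d1", "d2"), c("d1", "d2"), stages = stages)
  for (agg in c("union", "worst", "best")) {
    expect_identical(
      grade_pair(mk$annotations, "gene1", "gene2", "t1", aggregation = agg),
      "equal")
  }
})

test_that("worst/best aggregation bracket stagewise divergence", {
  # equal at TS15, disjoint at TS17
  ann <- rbind(
    make_pair_annotations("d1", "d1", stages = list("TS15", "TS15"))$annotations,
    make_pair_annotations("d2", "d3", stages = list("TS17", "TS17"))$annotations)
  expect_identical(grade_pair(ann, "gene1", "gene2", "t1", aggregation = "worst"),
                   "diff_domain")
  expect_identical(grade_pair(ann, "gene1", "gene2", "t1", aggregation = "best"),
                   "equal")
  # union pools domains: {d1,d2} vs {d1,d3} overlap
  expect_identical(grade_pair(ann, "gene1", "gene2", "t1", aggregation = "union"),
                   "minor_diff")
})

test_that("presence-absence is consistent with exclusive grading", {
  set.seed(7)
  sim <- simulate_expression(theta = 0.4, seed = 7)
  m <- build_presence_matrix(sim$annotations, sim$territories,
                             genes = sim$genes$gene)
  for (sf in unique(sim$genes$subfamily)[1:2]) {
    reg <- sim$genes[sim$genes$subfamily == sf, ]
    res <- compare_subfamily(sim$annotations, sf, sim$territories,
                             sim$stage_map, genes = sim$genes)
    for (i in seq_len(nrow(res$grid))) {
      row <- res$grid[i, ]
      pair <- res$pairs[[row$comparison]]
      present <- m[pair, row$territory_id]
      if (sum(present) == 0L) expect_identical(row$grade, "not_applicable")
      if (sum(present) == 1L) expect_identical(row$grade, "exclusive")
      if (row$grade %in% c("equal", "minor_diff", "diff_domain")) {
        expect_identical(unname(present), c(1L, 1L))
      }
    }
  }
})

test_that("compare_subfamily reproduces the limb-ectoderm paralogue contrast", {
  terr <- data.frame(id = "limb_ectoderm", name = "limb ectoderm",
                     stringsAsFactors = FALSE)
  mk <- function(gene, sp, tag, stage, dom) {
    data.frame(gene = gene, species = sp, subfamily = "Wnt7",
               paralogue_tag = tag, stage = stage,
               territory_id = "limb_ectoderm", domains = dom,
               stringsAsFactors = FALSE)
  }
  ann <- rbind(mk("mouse_Wnt7a", "mouse", "a", "TS15", "dorsal_ectoderm"),
               mk("mouse_Wnt7b", "mouse", "b", "TS15", "proximoventral_ectoderm"),
               mk("chick_Wnt7a", "chick", "a", "HH20", "dorsal_ectoderm"),
               mk("chick_Wnt7b", "chick", "b", "HH20", "proximoventral_ectoderm"))
  res <- compare_subfamily(ann, "Wnt7", terr, default_stage_map())
  g <- function(kind) res$grid$grade[res$grid$comparison == kind]
  expect_identical(g("orthologues_a"), "equal")
  expect_identical(g("orthologues_b"), "equal")
  expect_identical(g("paralogues_s1"), "diff_domain")
  expect_identical(g("paralogues_s2"), "diff_domain")
  expect_equal(unname(res$divergence_index[c("orthologues_a", "paralogues_s1")]),
               c(0, 2))
})

test_that("incomplete subfamilies and empty grids are handled", {
  terr <- data.frame(id = "t1", name = "t1", stringsAsFactors = FALSE)
  ann <- data.frame(gene = "only_one", species = "mouse", subfamily = "Wnt9",
                    paralogue_tag = "a", stage = "TS15", territory_id = "t1",
                    domains = "d1", stringsAsFactors = FALSE)
  expect_error(compare_subfamily(ann, "Wnt9", terr),
               class = "paradiv_validation_error")

  # four registered genes, zero annotations: empty grid, index undefined
  reg <- data.frame(gene = paste0("g", 1:4),
                    species = rep(c("mouse", "chick"), each = 2),
                    subfamily = "Wnt9", paralogue_tag = rep(c("a", "b"), 2),
                    stringsAsFactors = FALSE)
  res <- compare_subfamily(ann[0, ], "Wnt9", terr, genes = reg)
  expect_identical(nrow(res$grid), 0L)
  expect_true(all(is.na(res$divergence_index)))
  expect_error(divergence_index(res, "orthologues_a"),
               class = "paradiv_validation_error")
})

test_that("divergence index is the mean ordinal over applicable cells", {
  expect_equal(mean(grade_value(c("equal", "diff_domain", "exclusive"))), 5 / 3)
  expect_equal(grade_value("equal"), 0)
  expect_equal(grade_value("exclusive"), 3)
  expect_true(is.na(grade_value("not_applicable")))
})
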