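# Independent brute-force re-implementations used as oracles. These are
# deliberately written as flat nested conditionals over explicit residue
# comparisons, sharing no code with the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# identity-matching column classifier, returning list(category, divergent_role)
oracle_classify <- function(col) {
  a <- col[["outgroup"]]
  if (a == "-") return(list(category = "outgroup_gap", divergent_role = NA_character_))
  if (col[["s1a"]] == "C" && col[["s1b"]] == "C" && col[["s2a"]] == "C" &&
      col[["s2b"]] == "C" && a == "C") {
    return(list(category = "conserved_cys", divergent_role = NA_character_))
  }
  hit <- function(r) col[[r]] != "-" && col[[r]] == a
  h1a <- hit("s1a"); h1b <- hit("s1b"); h2a <- hit("s2a"); h2b <- hit("s2b")
  n <- h1a + h1b + h2a + h2b
  if (n == 4) return(list(category = "fully_conserved", divergent_role = NA_character_))
  if (n == 3) {
    who <- if (!h1a) "s1a" else if (!h1b) "s1b" else if (!h2a) "s2a" else "s2b"
    return(list(category = "single_gene_divergent", divergent_role = who))
  }
  if (h1a && h2a && !h1b && !h2b) {
    return(list(category = "paralogue_a_conserved", divergent_role = NA_character_))
  }
  if (h1b && h2b && !h1a && !h2a) {
    return(list(category = "paralogue_b_conserved", divergent_role = NA_character_))
  }
  if (n == 0) {
    v <- c(col[["s1a"]], col[["s1b"]], col[["s2a"]], col[["s2b"]])
    if (!any(v == "-") && v[1] == v[2] && v[2] == v[3] && v[3] == v[4]) {
      return(list(category = "vertebrate_only", divergent_role = NA_character_))
    }
  }
  list(category = "unclassified", divergent_role = NA_character_)
}

# random five-residue column (never all-gap)
random_column <- function(p_gap = 0.1) {
  repeat {
    col <- sample(c(AA20, "-"), 5, replace = TRUE,
                  prob = c(rep((1 - p_gap) / 20, 20), p_gap))
    if (!all(col == "-")) break
  }
  names(col) <- seq_roles()
  col
}

# double-loop subset-testing oracle for the sharing report
oracle_sharing <- function(m) {
  terr <- colnames(m)
  sets <- lapply(terr, function(t) rownames(m)[m[, t] == 1])
  names(sets) <- terr
  rows <- list()
  excluded <- character(0)
  for (t in terr) {
    if (length(sets[[t]]) == 0) {
      excluded <- c(excluded, t)
      next
    }
    shared <- character(0)
    all_equal <- TRUE
    for (u in terr) {
      if (u == t) next
      if (all(sets[[t]] %in% sets[[u]])) {
        shared <- c(shared, u)
        if (!(all(sets[[u]] %in% sets[[t]]))) all_equal <- FALSE
      }
    }
    rows[[t]] <- list(shared_with = shared,
                      reciprocal = if (all_equal) "R" else "NR")
  }
  list(rows = rows, excluded = excluded)
}

random_presence_matrix <- function(max_dim = 12L, p = 0.4) {
  g <- sample.int(max_dim, 1)
  t <- sample.int(max_dim, 1)
  m <- matrix(rbinom(g * t, 1, p), nrow = g,
              dimnames = list(paste0("g", seq_len(g)), paste0("t", seq_len(t))))
  storage.mode(m) <- "integer"
  m
}

# minimal annotation table: one row per (gene, stage, territory) with the
# given domain sets; both genes same species unless species given
make_pair_annotations <- function(d1, d2, territory = "t1",
                                  species = c("mouse", "mouse"),
                                  stages = list("TS15", "TS15")) {
  rows <- list()
  add <- function(gene, sp, tag, d, stg) {
    if (!length(d)) return()
    for (s in stg) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = gene, species = sp, subfamily = "WntX", paralogue_tag = tag,
        stage = s, territory_id = territory,
        domains = paste(d, collapse = ";"), level = "strong",
        stringsAsFactors = FALSE)
    }
  }
  add("gene1", species[1], "a", d1, stages[[1]])
  add("gene2", species[2], "b", d2, stages[[2]])
  reg <- data.frame(gene = c("gene1", "gene2"), species = species,
                    subfamily = "WntX", paralogue_tag = c("a", "b"),
                    stringsAsFactors = FALSE)
  if (length(rows)) {
    list(annotations = do.call(rbind, rows), genes = reg)
  } else {
    list(annotations = data.frame(gene = character(0), species = character(0),
                                  subfamily = character(0),
                                  paralogue_tag = character(0),
                                  stage = character(0),
                                  territory_id = character(0),
                                  domains = character(0), level = character(0),
                                  stringsAsFactors = FALSE),
         genes = reg)
  }
}

# grade_pair on bare domain sets, routed through a real annotation table
grade_sets_via_pair <- function(d1, d2, aggregation = "union") {
  mk <- make_pair_annotations(d1, d2)
  grade_pair(mk$annotations, "gene1", "gene2", "t1", aggregation = aggregation)
}
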