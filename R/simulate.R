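#' Default embryonic territory vocabulary
#'
#' A controlled vocabulary of the anatomical territories typically scored in
#' whole-embryo expression surveys of mid-gestation amniote embryos: the
#' major CNS subdivisions, branchial arches 1-4, limb ectoderm and
#' mesenchyme, facial structures, and the principal organ systems. Parent
#' links group subdivisions (e.g. all brain vesicles under `cns`).
#'
#' @return Data frame with columns `id`, `name`, `parent_id`.
#' @export
default_territory_vocabulary <- function() {
  t <- function(id, name, parent = NA_character_) {
    data.frame(id = id, name = name, parent_id = parent, stringsAsFactors = FALSE)
  }
  rbind(
    t("cns", "central nervous system"),
    t("telencephalon", "telencephalon", "cns"),
    t("diencephalon", "diencephalon", "cns"),
    t("mesencephalon", "mesencephalon", "cns"),
    t("rhombencephalon", "rhombencephalon", "cns"),
    t("neural_tube", "neural tube", "cns"),
    t("eye", "eye"),
    t("otic_vesicle", "otic vesicle"),
    t("frontonasal_process", "frontonasal process"),
    t("branchial_arch_1", "branchial arch 1"),
    t("branchial_arch_2", "branchial arch 2"),
    t("branchial_arch_3", "branchial arch 3"),
    t("branchial_arch_4", "branchial arch 4"),
    t("limb_ectoderm", "limb ectoderm"),
    t("limb_mesenchyme", "limb mesenchyme"),
    t("somites", "somites"),
    t("heart", "heart"),
    t("lung", "lung"),
    t("gut", "gut"),
    t("genitourinary", "genitourinary system"),
    t("tail_bud", "tail bud")
  )
}

#' Simulate a subfamily alignment with planted column classes
#'
#' Draws a conservation category for every column from `class_mix` and
#' constructs residues that satisfy exactly that category under identity
#' matching: e.g. a `single_gene_divergent` column picks a uniformly random
#' vertebrate gene and gives it a residue differing from the outgroup's. The
#' same seed always yields the identical alignment.
#'
#' @param n_columns Number of columns to generate.
#' @param class_mix Named numeric vector of category proportions (must sum to
#'   1). Categories are restricted to the constructible ones — every category
#'   of [column_categories()] except `unclassified`.
#' @param seed Integer seed for the generator's random stream.
#' @param subfamily Name recorded on the alignment.
#' @return List with `alignment` (a [subfamily_alignment()]) and `labels`
#'   (data frame `column`, `category`, `divergent_role` — the planted truth).
#' @export
#' @examples
#' sim <- simulate_alignment(20, c(fully_conserved = 0.5,
#'                                 single_gene_divergent = 0.5), seed = 7)
#' table(sim$labels$category)
simulate_alignment <- function(n_columns,
                               class_mix = c(conserved_cys = 0.08,
                                             fully_conserved = 0.52,
                                             single_gene_divergent = 0.12,
                                             paralogue_a_conserved = 0.06,
                                             paralogue_b_conserved = 0.06,
                                             vertebrate_only = 0.08,
                                             outgroup_gap = 0.08),
                               seed = 1L, subfamily = "simulated") {
  allowed <- setdiff(column_categories(), "unclassified")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% allowed)) {
    pd_validation_error(sprintf("class_mix categories must be among: %s",
                                paste(allowed, collapse = ", ")))
  }
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8) {
    pd_validation_error("class_mix proportions must be non-negative and sum to 1")
  }
  stopifnot(n_columns >= 1L)
  set.seed(as.integer(seed))
  roles <- seq_roles()
  vert <- vertebrate_roles()
  category <- sample(names(class_mix), n_columns, replace = TRUE,
                     prob = class_mix)
  mat <- matrix(NA_character_, nrow = 5L, ncol = n_columns,
                dimnames = list(roles, NULL))
  divergent <- rep(NA_character_, n_columns)
  for (j in seq_len(n_columns)) {
    col <- switch(category[[j]],
      conserved_cys = setNames(rep("C", 5), roles),
      fully_conserved = {
        r <- sample(setdiff(AA_LETTERS, "C"), 1)
        setNames(rep(r, 5), roles)
      },
      single_gene_divergent = {
        base <- sample(AA_LETTERS, 1)
        who <- sample(vert, 1)
        divergent[[j]] <- who
        col <- setNames(rep(base, 5), roles)
        col[[who]] <- sample(setdiff(AA_LETTERS, base), 1)
        col
      },
      paralogue_a_conserved = {
        base <- sample(AA_LETTERS, 1)
        col <- setNames(rep(base, 5), roles)
        col[c("s1b", "s2b")] <- sample(setdiff(AA_LETTERS, base), 2, replace = TRUE)
        col
      },
      paralogue_b_conserved = {
        base <- sample(AA_LETTERS, 1)
        col <- setNames(rep(base, 5), roles)
        col[c("s1a", "s2a")] <- sample(setdiff(AA_LETTERS, base), 2, replace = TRUE)
        col
      },
      vertebrate_only = {
        v <- sample(AA_LETTERS, 1)
        col <- setNames(rep(v, 5), roles)
        col[["outgroup"]] <- sample(setdiff(AA_LETTERS, v), 1)
        col
      },
      outgroup_gap = {
        col <- setNames(c(GAP, sample(AA_LETTERS, 4, replace = TRUE)), roles)
        col
      })
    mat[, j] <- col[roles]
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  list(alignment = subfamily_alignment(setNames(seqs, roles), subfamily = subfamily),
       labels = data.frame(column = seq_len(n_columns), category = category,
                           divergent_role = divergent, stringsAsFactors = FALSE))
}

#' Simulate expression annotations with planted similarity grades
#'
#' A generative model of a paralogue-pair expression survey. For each
#' subfamily and territory, with probability `p_express` an ancestral domain
#' set is drawn from the territory's domain pool; each of the four subfamily
#' genes (two species x paralogues "a"/"b") inherits it. Then, independently
#' per gene and territory, with probability `theta` exactly one mutation is
#' applied, chosen uniformly among the three kinds that map one-to-one onto
#' grade outcomes: drop all domains (loss of the territory), replace the set
#' with a disjoint one (domain shift), or add/remove one domain (minor
#' modification). The planted grade of each paralogue/orthologue pair is the
#' grade implied by the two final domain sets, so planted truth is
#' unambiguous. Domain sets are constant across a gene's three stages.
#'
#' `theta` is the divergence dial: at 0 every applicable comparison is
#' `equal`; pattern divergence increases monotonically in expectation with
#' `theta`.
#'
#' @param territories Territory vocabulary data frame; defaults to
#'   [default_territory_vocabulary()] minus grouping-only entries.
#' @param subfamilies Character vector of subfamily names.
#' @param species Length-2 character vector; must match the columns of
#'   `stage_map`.
#' @param stage_map Stage-correspondence data frame, one column per species.
#' @param p_express Probability a (subfamily, territory) is ancestrally
#'   occupied.
#' @param theta Per-gene, per-territory mutation probability in [0, 1].
#' @param n_domains_per_territory Size of each territory's primary domain
#'   pool (a disjoint pool of equal size backs the replacement mutation).
#' @param mutation_kinds Which mutation kinds may be drawn; any non-empty
#'   subset of `c("drop", "replace", "minor")`. Restricting the set forces a
#'   single divergence mode (e.g. drop-only to study territory loss).
#' @param theta_genes Optional character vector restricting mutation to the
#'   named genes; all other genes keep the ancestral set unchanged.
#' @param seed Integer seed.
#' @return List with `annotations` (annotation data frame), `genes` (full
#'   gene registry incl. genes left without annotations), `territories`,
#'   `stage_map`, `truth` (data frame `subfamily`, `territory_id`,
#'   `comparison`, `grade` — the planted grades for every territory where
#'   any of the four genes is expressed), and `config`.
#' @export
simulate_expression <- function(territories = NULL,
                                subfamilies = c("Wnt2", "Wnt5", "Wnt7", "Wnt8"),
                                species = c("mouse", "chick"),
                                stage_map = default_stage_map(),
                                p_express = 0.5,
                                theta = 0.2,
                                n_domains_per_territory = 3L,
                                mutation_kinds = c("drop", "replace", "minor"),
                                theta_genes = NULL,
                                seed = 1L) {
  mutation_kinds <- match.arg(mutation_kinds, c("drop", "replace", "minor"),
                              several.ok = TRUE)
  if (is.null(territories)) {
    vocab <- default_territory_vocabulary()
    territories <- vocab[vocab$id != "cns", , drop = FALSE]  # leaves only
  }
  if (!nrow(territories)) pd_validation_error("territory vocabulary is empty")
  if (p_express < 0 || p_express > 1 || theta < 0 || theta > 1) {
    pd_validation_error("p_express and theta must be probabilities in [0, 1]")
  }
  validate_stage_map(stage_map)
  if (!setequal(names(stage_map), species)) {
    names(stage_map) <- species
  }
  set.seed(as.integer(seed))
  nd <- as.integer(n_domains_per_territory)
  stopifnot(nd >= 1L)

  genes <- do.call(rbind, lapply(subfamilies, function(sf) {
    do.call(rbind, lapply(species, function(sp) {
      data.frame(gene = paste0(sp, "_", sf, c("a", "b")), species = sp,
                 subfamily = sf, paralogue_tag = c("a", "b"),
                 stringsAsFactors = FALSE)
    }))
  }))

  ann_rows <- list()
  truth_rows <- list()
  for (sf in subfamilies) {
    reg <- genes[genes$subfamily == sf, , drop = FALSE]
    for (t in territories$id) {
      if (runif(1) >= p_express) next
      pool <- paste0(t, "_d", seq_len(nd))
      alt_pool <- paste0(t, "_x", seq_len(nd))
      ancestral <- sample(pool, sample.int(nd, 1))
      final <- setNames(vector("list", 4L), reg$gene)
      for (g in reg$gene) {
        d <- ancestral
        mutable <- is.null(theta_genes) || g %in% theta_genes
        if (mutable && runif(1) < theta) {
          kind <- if (length(mutation_kinds) == 1L) mutation_kinds else
            sample(mutation_kinds, 1)
          d <- switch(kind,
            drop = character(0),
            replace = sample(alt_pool, sample.int(nd, 1)),
            minor = {
              if (length(d) > 1L && runif(1) < 0.5) {
                d[-sample.int(length(d), 1)]
              } else {
                c(d, sample(setdiff(c(pool, alt_pool), d), 1))
              }
            })
        }
        final[[g]] <- sort(d)
      }
      if (!any(lengths(final) > 0L)) next
      # annotation rows: one per stage for each expressing gene
      for (i in seq_len(nrow(reg))) {
        g <- reg$gene[i]
        if (!length(final[[g]])) next
        lvl <- sample(c("strong", "moderate", "weak"), 1)
        stages <- stage_map[[reg$species[i]]]
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          gene = g, species = reg$species[i], subfamily = sf,
          paralogue_tag = reg$paralogue_tag[i], stage = stages,
          territory_id = t, domains = join_domains(list(final[[g]])),
          level = lvl, stringsAsFactors = FALSE)
      }
      pick <- function(sp, tag) reg$gene[reg$species == sp & reg$paralogue_tag == tag]
      pairs <- list(
        paralogues_s1 = c(pick(species[1], "a"), pick(species[1], "b")),
        paralogues_s2 = c(pick(species[2], "a"), pick(species[2], "b")),
        orthologues_a = c(pick(species[1], "a"), pick(species[2], "a")),
        orthologues_b = c(pick(species[1], "b"), pick(species[2], "b")))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subfamily = sf, territory_id = t, comparison = names(pairs),
        grade = vapply(pairs, function(p)
          grade_domain_sets(final[[p[1]]], final[[p[2]]]), character(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  empty_ann <- data.frame(gene = character(0), species = character(0),
                          subfamily = character(0), paralogue_tag = character(0),
                          stage = character(0), territory_id = character(0),
                          domains = character(0), level = character(0),
                          stringsAsFactors = FALSE)
  annotations <- if (length(ann_rows)) do.call(rbind, ann_rows) else empty_ann
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(subfamily = character(0), territory_id = character(0),
               comparison = character(0), grade = character(0),
               stringsAsFactors = FALSE)
  list(annotations = annotations, genes = genes, territories = territories,
       stage_map = stage_map, truth = truth,
       config = list(subfamilies = subfamilies, species = species,
                     p_express = p_express, theta = theta,
                     n_domains_per_territory = nd,
                     mutation_kinds = mutation_kinds,
                     theta_genes = theta_genes, seed = as.integer(seed)))
}

#' Write a simulated expression dataset to disk
#'
#' Emits exactly the interchange files the analysis functions consume:
#' `annotations.tsv`, `territories.tsv`, `stage_map.tsv`, plus the planted
#' truth as `truth.json`.
#'
#' @param sim Result of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_expression_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotations = file.path(dir, "annotations.tsv"),
             territories = file.path(dir, "territories.tsv"),
             stage_map = file.path(dir, "stage_map.tsv"),
             truth = file.path(dir, "truth.json"))
  write.table(sim$annotations, paths[["annotations"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$territories, paths[["territories"]], sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(sim$stage_map, paths[["stage_map"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(truth = sim$truth, config = sim$config),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(paths)
}
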