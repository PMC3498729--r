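#' Ordinal similarity grades for expression patterns
#'
#' Two genes' spatial expression patterns within one anatomical territory are
#' graded on an ordinal scale:
#' \describe{
#'   \item{`equal` (symbol `=`, ordinal 0)}{expressed in equivalent domains.}
#'   \item{`minor_diff` (`*`, 1)}{same territory, overlapping but unequal
#'     domain sets.}
#'   \item{`diff_domain` (`**`, 2)}{same territory, disjoint domain sets.}
#'   \item{`exclusive` (`***`, 3)}{only one of the two genes is expressed in
#'     the territory.}
#'   \item{`not_applicable` (`.`)}{neither gene is expressed there.}
#' }
#'
#' @return Character vector of the grade codes in ordinal order, with
#'   `not_applicable` last.
#' @export
similarity_grades <- function() {
  c("equal", "minor_diff", "diff_domain", "exclusive", "not_applicable")
}

GRADE_VALUES <- c(equal = 0, minor_diff = 1, diff_domain = 2, exclusive = 3,
                  not_applicable = NA_real_)
GRADE_SYMBOLS <- c(equal = "=", minor_diff = "*", diff_domain = "**",
                   exclusive = "***", not_applicable = ".")

#' Ordinal value and display symbol of a similarity grade
#'
#' @param grade Character vector of grade codes.
#' @return `grade_value()`: numeric 0-3 (`NA` for `not_applicable`);
#'   `grade_symbol()`: the literal symbols `=`, `*`, `**`, `***` (`.` for
#'   `not_applicable`).
#' @export
grade_value <- function(grade) unname(GRADE_VALUES[grade])

#' @rdname grade_value
#' @export
grade_symbol <- function(grade) unname(GRADE_SYMBOLS[grade])

# The core set-comparison rule shared by grading and the generator's planted
# truth: grades are a pure function of the two (aggregated) domain sets.
grade_domain_sets <- function(d1, d2) {
  d1 <- unique(d1); d2 <- unique(d2)
  if (!length(d1) && !length(d2)) return("not_applicable")
  if (!length(d1) || !length(d2)) return("exclusive")
  if (!length(intersect(d1, d2))) return("diff_domain")
  if (setequal(d1, d2)) return("equal")
  "minor_diff"
}

#' Default mouse/chick stage correspondence
#'
#' The three matched embryonic stages used for cross-species comparison:
#' Theiler stages TS15, TS17, TS19 in the mouse against Hamburger-Hamilton
#' stages HH20, HH23, HH26 in the chick.
#'
#' @return Data frame with columns `mouse` and `chick`, one row per matched
#'   stage pair.
#' @export
default_stage_map <- function() {
  data.frame(mouse = c("TS15", "TS17", "TS19"),
             chick = c("HH20", "HH23", "HH26"),
             stringsAsFactors = FALSE)
}

validate_stage_map <- function(stage_map) {
  if (!is.data.frame(stage_map) || ncol(stage_map) != 2L) {
    pd_validation_error("stage map must be a two-column data frame (one column per species)")
  }
  if (anyDuplicated(stage_map[[1]]) || anyDuplicated(stage_map[[2]])) {
    pd_validation_error("stage map must be bijective over the listed stages")
  }
  invisible(stage_map)
}

#' Validate an expression annotation table
#'
#' An annotation table is the atomized form of a stage-by-territory
#' expression description: one row per (gene, stage, territory) presence
#' record, with the localized subdomains as a semicolon-separated set.
#' Required columns: `gene`, `species`, `subfamily`, `paralogue_tag` (one of
#' `"a"`/`"b"`), `stage`, `territory_id`, `domains` (non-empty). An optional
#' `level` column (`strong`/`moderate`/`weak`) is carried but ignored by
#' grading, which is purely spatial.
#'
#' @param annotations Data frame as above.
#' @param territories Optional territory vocabulary (data frame with an `id`
#'   column); if given, all `territory_id`s must resolve.
#' @return The validated data frame, invisibly.
#' @export
validate_annotations <- function(annotations, territories = NULL) {
  req <- c("gene", "species", "subfamily", "paralogue_tag", "stage",
           "territory_id", "domains")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) {
    pd_validation_error(sprintf("annotation table lacks column(s): %s",
                                paste(miss, collapse = ", ")))
  }
  empty <- which(!nzchar(annotations$domains) | is.na(annotations$domains))
  if (length(empty)) {
    pd_validation_error(sprintf(
      "annotation row(s) %s have an empty domain set; presence implies at least one domain",
      paste(empty, collapse = ", ")))
  }
  bad_tag <- setdiff(unique(annotations$paralogue_tag), c("a", "b"))
  if (length(bad_tag)) {
    pd_validation_error(sprintf("paralogue_tag must be 'a' or 'b' (got: %s)",
                                paste(bad_tag, collapse = ", ")))
  }
  if (!is.null(territories)) {
    unknown <- setdiff(unique(annotations$territory_id), territories$id)
    if (length(unknown)) {
      pd_validation_error(sprintf("unknown territory id(s): %s",
                                  paste(unknown, collapse = ", ")))
    }
  }
  invisible(annotations)
}

#' Gene registry of an annotation table
#'
#' @param annotations Annotation data frame.
#' @return Data frame of the distinct (gene, species, subfamily,
#'   paralogue_tag) combinations, in order of first appearance.
#' @export
gene_registry <- function(annotations) {
  cols <- c("gene", "species", "subfamily", "paralogue_tag")
  unique(annotations[cols])
}

# Domain set of one gene in one territory, optionally restricted to a stage
# subset; union over the retained stages.
domain_set <- function(annotations, gene, territory_id, stages = NULL) {
  keep <- annotations$gene == gene & annotations$territory_id == territory_id
  if (!is.null(stages)) keep <- keep & annotations$stage %in% stages
  rows <- annotations$domains[keep]
  if (!length(rows)) return(character(0))
  sort(unique(unlist(split_domains(rows))))
}

#' Build a binary gene-by-territory presence matrix
#'
#' A gene is marked present in a territory if it has any annotation there at
#' any stage (union over stages): detection at a single stage suffices.
#'
#' @param annotations Annotation data frame (see [validate_annotations()]).
#' @param territories Territory vocabulary data frame with an `id` column;
#'   fixes column order.
#' @param genes Optional character vector fixing row order; defaults to the
#'   genes of [gene_registry()] in order of first appearance.
#' @return Binary integer matrix, genes as rows, territories as columns.
#' @export
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g2"), species = "mouse",
#'                   subfamily = "Wnt2", paralogue_tag = c("a", "b", "b"),
#'                   stage = "TS15", territory_id = c("t1", "t1", "t2"),
#'                   domains = "d1")
#' terr <- data.frame(id = c("t1", "t2"), name = c("t1", "t2"))
#' build_presence_matrix(ann, terr, genes = c("g1", "g2", "g3"))
build_presence_matrix <- function(annotations, territories, genes = NULL) {
  validate_annotations(annotations, territories)
  if (is.null(genes)) genes <- unique(annotations$gene)
  m <- matrix(0L, nrow = length(genes), ncol = nrow(territories),
              dimnames = list(genes, territories$id))
  hit <- annotations$gene %in% genes
  if (any(hit)) {
    idx <- cbind(match(annotations$gene[hit], genes),
                 match(annotations$territory_id[hit], territories$id))
    m[idx] <- 1L
  }
  m
}

#' Grade the similarity of two genes' expression in one territory
#'
#' Compares the two genes' subdomain sets within the territory and returns an
#' ordinal grade (see [similarity_grades()]). With `aggregation = "union"`
#' each gene's domains are first pooled across all its stages; the per-stage
#' modes grade each matched stage separately and report the worst
#' (most divergent) or best grade across stages. Cross-species comparisons
#' need a stage map to pair the two species' stage series.
#'
#' The decision rule, applied to the (aggregated) domain sets D1, D2:
#' both empty, `not_applicable`; exactly one empty, `exclusive`; disjoint,
#' `diff_domain`; equal, `equal`; overlapping but unequal, `minor_diff`.
#' The result is symmetric in the two genes.
#'
#' @param annotations Annotation data frame.
#' @param gene1,gene2 Gene labels present in the table's registry.
#' @param territory_id Territory to compare in.
#' @param stage_map Two-column stage-correspondence data frame; required when
#'   the genes belong to different species.
#' @param aggregation `"union"` (default), `"worst"`, or `"best"`.
#' @return A grade code (length-1 character).
#' @export
grade_pair <- function(annotations, gene1, gene2, territory_id,
                       stage_map = NULL,
                       aggregation = c("union", "worst", "best")) {
  aggregation <- match.arg(aggregation)
  reg <- gene_registry(annotations)
  sp1 <- reg$species[match(gene1, reg$gene)]
  sp2 <- reg$species[match(gene2, reg$gene)]
  cross <- !is.na(sp1) && !is.na(sp2) && sp1 != sp2
  if (cross && is.null(stage_map)) {
    pd_abort("cross-species comparison requires a stage map",
             class = "configuration_error")
  }
  if (!is.null(stage_map)) validate_stage_map(stage_map)

  if (aggregation == "union") {
    d1 <- domain_set(annotations, gene1, territory_id)
    d2 <- domain_set(annotations, gene2, territory_id)
    return(grade_domain_sets(d1, d2))
  }

  # per-stage grading over matched stage pairs
  if (cross) {
    sp_cols <- names(stage_map)
    c1 <- if (!is.na(match(sp1, sp_cols))) match(sp1, sp_cols) else 1L
    c2 <- if (c1 == 1L) 2L else 1L
    pairs <- Map(c, stage_map[[c1]], stage_map[[c2]])
  } else {
    stages <- sort(unique(annotations$stage[annotations$gene %in% c(gene1, gene2) &
                                              annotations$territory_id == territory_id]))
    if (!length(stages)) return("not_applicable")
    pairs <- Map(c, stages, stages)
  }
  per_stage <- vapply(pairs, function(p) {
    grade_domain_sets(domain_set(annotations, gene1, territory_id, p[[1]]),
                      domain_set(annotations, gene2, territory_id, p[[2]]))
  }, character(1))
  per_stage <- per_stage[per_stage != "not_applicable"]
  if (!length(per_stage)) return("not_applicable")
  vals <- grade_value(per_stage)
  pick <- if (aggregation == "worst") which.max(vals) else which.min(vals)
  per_stage[[pick]]
}

comparison_kinds <- function() {
  c("paralogues_s1", "paralogues_s2", "orthologues_a", "orthologues_b")
}

#' Four-way paralogue/orthologue comparison of one subfamily
#'
#' For a subfamily with two paralogues ("a", "b") in each of two species,
#' grades four comparisons in every territory where any of the pair is
#' expressed: the paralogue pair within each species, and the "a" and "b"
#' orthologue pairs across species. Each comparison column is summarised by a
#' divergence index, the mean ordinal grade over applicable territories
#' (0 = identical patterns, 3 = fully exclusive patterns).
#'
#' @param annotations Annotation data frame.
#' @param subfamily Subfamily name to compare.
#' @param territories Territory vocabulary data frame (`id` column fixes row
#'   order).
#' @param stage_map Stage-correspondence data frame (see
#'   [default_stage_map()]).
#' @param aggregation Stage aggregation mode, as in [grade_pair()].
#' @param genes Optional gene registry data frame (columns `gene`, `species`,
#'   `subfamily`, `paralogue_tag`) declaring the subfamily's four genes even
#'   if some have no annotations; defaults to the registry derived from
#'   `annotations`.
#' @return A `comparison_result`: list with `subfamily`, `species` (the two
#'   species in registry order), `genes` (the 2x2 registry), `grid` (long
#'   data frame: `territory_id`, `comparison`, `grade`), `divergence_index`
#'   (named numeric over the four comparison kinds; `NA` where no territory
#'   is applicable), and `aggregation`.
#' @export
compare_subfamily <- function(annotations, subfamily, territories,
                              stage_map = default_stage_map(),
                              aggregation = c("union", "worst", "best"),
                              genes = NULL) {
  aggregation <- match.arg(aggregation)
  validate_annotations(annotations, territories)
  reg <- if (is.null(genes)) gene_registry(annotations) else genes
  reg <- reg[reg$subfamily == subfamily, , drop = FALSE]
  species <- unique(reg$species)
  ok <- nrow(reg) == 4L && length(species) == 2L &&
    all(vapply(species, function(s) setequal(reg$paralogue_tag[reg$species == s],
                                             c("a", "b")), logical(1)))
  if (!ok) {
    pd_validation_error(sprintf(
      "incomplete subfamily '%s': need the 'a' and 'b' paralogues of two species (found %d gene(s))",
      subfamily, nrow(reg)))
  }
  pick <- function(sp, tag) reg$gene[reg$species == sp & reg$paralogue_tag == tag]
  pairs <- list(
    paralogues_s1 = c(pick(species[1], "a"), pick(species[1], "b")),
    paralogues_s2 = c(pick(species[2], "a"), pick(species[2], "b")),
    orthologues_a = c(pick(species[1], "a"), pick(species[2], "a")),
    orthologues_b = c(pick(species[1], "b"), pick(species[2], "b"))
  )
  sub_ann <- annotations[annotations$gene %in% reg$gene, , drop = FALSE]
  terr <- territories$id[territories$id %in% unique(sub_ann$territory_id)]
  grid <- do.call(rbind, lapply(terr, function(t) {
    data.frame(
      territory_id = t,
      comparison = comparison_kinds(),
      grade = vapply(pairs, function(p) {
        grade_pair(sub_ann, p[[1]], p[[2]], t, stage_map, aggregation)
      }, character(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(grid)) {
    grid <- data.frame(territory_id = character(0), comparison = character(0),
                       grade = character(0), stringsAsFactors = FALSE)
  }
  di <- vapply(comparison_kinds(), function(k) {
    vals <- grade_value(grid$grade[grid$comparison == k])
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }, numeric(1))
  structure(list(subfamily = subfamily, species = species, genes = reg,
                 pairs = pairs, grid = grid, divergence_index = di,
                 aggregation = aggregation),
            class = "comparison_result")
}

#' Divergence index of one comparison column
#'
#' The arithmetic mean of the ordinal grade values (0-3) over the applicable
#' (non-`not_applicable`) territories of one comparison kind.
#'
#' @param result A `comparison_result` from [compare_subfamily()].
#' @param kind One of `"paralogues_s1"`, `"paralogues_s2"`,
#'   `"orthologues_a"`, `"orthologues_b"`.
#' @return Numeric scalar in [0, 3].
#' @export
divergence_index <- function(result, kind) {
  stopifnot(inherits(result, "comparison_result"))
  kind <- match.arg(kind, comparison_kinds())
  vals <- grade_value(result$grid$grade[result$grid$comparison == kind])
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    pd_validation_error(sprintf("divergence index undefined for '%s': no applicable territories",
                                kind))
  }
  mean(vals)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Subfamily '%s' comparison (%s vs %s; %s aggregation)\n",
              x$subfamily, x$species[1], x$species[2], x$aggregation))
  cat(sprintf("  territories graded: %d\n", length(unique(x$grid$territory_id))))
  for (k in comparison_kinds()) {
    p <- x$pairs[[k]]
    di <- x$divergence_index[[k]]
    cat(sprintf("  %-14s %s vs %s: divergence index %s\n", k, p[1], p[2],
                if (is.na(di)) "n/a" else sprintf("%.2f", di)))
  }
  invisible(x)
}

#' Read/write the tabular interchange files of the expression model
#'
#' `read_annotations()` reads an annotation TSV (columns as in
#' [validate_annotations()]); `read_territories()` a territory vocabulary TSV
#' (`id`, `name`, optional `parent_id`); `read_stage_map()` a two-column
#' stage-correspondence TSV; `read_presence_matrix()` /
#' `write_presence_matrix()` round-trip the binary gene-by-territory matrix
#' (genes as rows, first column `gene`).
#'
#' @param path File path.
#' @return The corresponding data frame or matrix.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) pd_io_error(sprintf("annotation file not found: %s", path))
  ann <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  validate_annotations(ann)
  ann
}

#' @rdname read_annotations
#' @export
read_territories <- function(path) {
  if (!file.exists(path)) pd_io_error(sprintf("territory vocabulary not found: %s", path))
  terr <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     colClasses = "character")
  if (!all(c("id", "name") %in% names(terr))) {
    pd_validation_error("territory vocabulary must have columns 'id' and 'name'")
  }
  if (anyDuplicated(terr$id)) pd_validation_error("territory ids must be unique")
  terr
}

#' @rdname read_annotations
#' @export
read_stage_map <- function(path) {
  if (!file.exists(path)) pd_io_error(sprintf("stage map not found: %s", path))
  sm <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  validate_stage_map(sm)
  sm
}

#' @rdname read_annotations
#' @param matrix Binary gene-by-territory matrix with dimnames.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
read_presence_matrix <- function(path) {
  if (!file.exists(path)) pd_io_error(sprintf("presence matrix not found: %s", path))
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
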