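#' Classify one alignment column into a conservation category
#'
#' Applies a fixed decision tree, in priority order:
#' \enumerate{
#'   \item outgroup residue is a gap: `outgroup_gap`;
#'   \item all five residues are cysteine: `conserved_cys`;
#'   \item otherwise let M be the set of vertebrate roles whose residue
#'     matches the outgroup residue under the policy (a gap never matches):
#'     all four match, `fully_conserved`; exactly three match,
#'     `single_gene_divergent` with the non-matching role recorded; M is
#'     exactly the two "a" roles, `paralogue_a_conserved`; exactly the two
#'     "b" roles, `paralogue_b_conserved`; no role matches but the four
#'     vertebrate residues are non-gap and mutually equal, `vertebrate_only`;
#'     anything else, `unclassified`.
#' }
#'
#' @param column Named character vector of five single residues; names are
#'   the role codes of [seq_roles()].
#' @param policy A [match_policy()]; defaults to identity matching.
#' @return List with elements `category` (one of [column_categories()]) and
#'   `divergent_role` (role code or `NA`; set only for
#'   `single_gene_divergent`).
#' @export
#' @examples
#' classify_column(c(outgroup = "K", s1a = "K", s1b = "K", s2a = "K", s2b = "R"))
classify_column <- function(column, policy = match_policy()) {
  roles <- seq_roles()
  if (!is.character(column) || is.null(names(column)) ||
      !setequal(names(column), roles) || anyDuplicated(names(column))) {
    pd_validation_error("malformed column: need exactly one residue per role")
  }
  column <- toupper(column[roles])
  check_residues(column)
  out <- column[["outgroup"]]
  if (out == GAP) {
    return(list(category = "outgroup_gap", divergent_role = NA_character_))
  }
  if (all(column == "C")) {
    return(list(category = "conserved_cys", divergent_role = NA_character_))
  }
  vert <- vertebrate_roles()
  m <- vert[vapply(vert, function(r) residues_match(column[[r]], out, policy),
                   logical(1))]
  cat_ <- if (length(m) == 4L) {
    "fully_conserved"
  } else if (length(m) == 3L) {
    "single_gene_divergent"
  } else if (setequal(m, c("s1a", "s2a"))) {
    "paralogue_a_conserved"
  } else if (setequal(m, c("s1b", "s2b"))) {
    "paralogue_b_conserved"
  } else if (length(m) == 0L && !any(column[vert] == GAP) &&
             length(unique(column[vert])) == 1L) {
    "vertebrate_only"
  } else {
    "unclassified"
  }
  list(category = cat_,
       divergent_role = if (cat_ == "single_gene_divergent") setdiff(vert, m) else NA_character_)
}

#' Percent similarity of one vertebrate sequence to the outgroup
#'
#' Computed over the columns where both the vertebrate sequence and the
#' outgroup are ungapped: 100 x matches / mutually-ungapped columns. Under an
#' `"identity"` policy this is percent identity; under `"groups"` it is
#' percent similarity in the conventional sense.
#'
#' @param aln A [subfamily_alignment()].
#' @param role One of the four vertebrate role codes.
#' @param policy A [match_policy()].
#' @return Numeric scalar in [0, 100].
#' @export
pairwise_similarity <- function(aln, role, policy = match_policy()) {
  stopifnot(inherits(aln, "subfamily_alignment"))
  if (!is_string(role) || !role %in% vertebrate_roles()) {
    pd_validation_error("`role` must be one of the four vertebrate roles")
  }
  a <- aln$residues["outgroup", ]
  b <- aln$residues[role, ]
  both <- a != GAP & b != GAP
  n <- sum(both)
  if (n == 0L) {
    pd_validation_error(sprintf(
      "similarity undefined: no mutually ungapped columns for role '%s'", role))
  }
  hits <- sum(mapply(residues_match, b[both], a[both],
                     MoreArgs = list(policy = policy)))
  100 * hits / n
}

#' Profile every column of a subfamily alignment
#'
#' Runs [classify_column()] over all columns and aggregates the summary
#' statistics: conserved-cysteine count, fully conserved sites,
#' paralogue-specific conservation counts, per-gene single-gene divergence
#' counts, and percent similarity of each vertebrate sequence to the
#' outgroup.
#'
#' @param aln A [subfamily_alignment()].
#' @param policy A [match_policy()].
#' @return A `conservation_profile` object: list with
#'   \describe{
#'     \item{subfamily}{subfamily name.}
#'     \item{columns}{data frame with `column` (1-based index), one residue
#'       column per role, `category`, `divergent_role`.}
#'     \item{n_conserved_cys, n_fully_conserved, n_paralogue_a_specific,
#'       n_paralogue_b_specific}{category counts.}
#'     \item{single_gene_divergence}{named integer vector over the four
#'       vertebrate roles.}
#'     \item{pairwise_similarity}{named numeric vector over the four
#'       vertebrate roles, percent.}
#'     \item{match_mode}{the policy mode used.}
#'   }
#' @export
#' @examples
#' aln <- subfamily_alignment(
#'   c(outgroup = "CKGT-A", s1a = "CKGNLA", s1b = "CKSNLA",
#'     s2a = "CKGNLA", s2b = "CRSNLV"),
#'   subfamily = "toy")
#' profile_alignment(aln)
profile_alignment <- function(aln, policy = match_policy()) {
  stopifnot(inherits(aln, "subfamily_alignment"))
  L <- ncol(aln$residues)
  cls <- vector("list", L)
  for (j in seq_len(L)) {
    cls[[j]] <- classify_column(aln$residues[, j], policy)
  }
  category <- vapply(cls, `[[`, character(1), "category")
  divergent <- vapply(cls, `[[`, character(1), "divergent_role")
  columns <- data.frame(column = seq_len(L),
                        t(aln$residues),
                        category = category,
                        divergent_role = divergent,
                        row.names = NULL,
                        stringsAsFactors = FALSE)
  sgd <- table(factor(divergent[category == "single_gene_divergent"],
                      levels = vertebrate_roles()))
  sims <- vapply(vertebrate_roles(), pairwise_similarity, numeric(1),
                 aln = aln, policy = policy)
  structure(list(
    subfamily = aln$subfamily,
    columns = columns,
    n_conserved_cys = sum(category == "conserved_cys"),
    n_fully_conserved = sum(category == "fully_conserved"),
    n_paralogue_a_specific = sum(category == "paralogue_a_conserved"),
    n_paralogue_b_specific = sum(category == "paralogue_b_conserved"),
    single_gene_divergence = setNames(as.integer(sgd), vertebrate_roles()),
    pairwise_similarity = sims,
    match_mode = policy$mode
  ), class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("Conservation profile of '%s' (%d columns, %s matching)\n",
              x$subfamily, nrow(x$columns), x$match_mode))
  cat(sprintf("  conserved cysteines:        %d\n", x$n_conserved_cys))
  cat(sprintf("  fully conserved sites:      %d\n", x$n_fully_conserved))
  cat(sprintf("  'a'-paralogue-specific:     %d\n", x$n_paralogue_a_specific))
  cat(sprintf("  'b'-paralogue-specific:     %d\n", x$n_paralogue_b_specific))
  cat("  single-gene divergence:     ",
      paste(sprintf("%s=%d", names(x$single_gene_divergence),
                    x$single_gene_divergence), collapse = " "), "\n")
  cat("  similarity vs outgroup (%): ",
      paste(sprintf("%s=%.1f", names(x$pairwise_similarity),
                    x$pairwise_similarity), collapse = " "), "\n")
  invisible(x)
}

#' Category counts of a conservation profile
#'
#' Tabulates every category (including `outgroup_gap` and `unclassified`);
#' counts always sum to the alignment length.
#'
#' @param profile A `conservation_profile`.
#' @return Named integer vector over [column_categories()].
#' @export
category_counts <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  tab <- table(factor(profile$columns$category, levels = column_categories()))
  setNames(as.integer(tab), column_categories())
}

#' Write a conservation profile to disk
#'
#' Emits the per-column classification as TSV and the summary statistics as
#' JSON into `dir`.
#'
#' @param profile A `conservation_profile`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_profile <- function(profile, dir) {
  stopifnot(inherits(profile, "conservation_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, sprintf("%s_columns.tsv", profile$subfamily))
  json <- file.path(dir, sprintf("%s_profile.json", profile$subfamily))
  write.table(profile$columns, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  jsonlite::write_json(list(
    subfamily = profile$subfamily,
    match_mode = profile$match_mode,
    n_columns = nrow(profile$columns),
    n_conserved_cys = profile$n_conserved_cys,
    n_fully_conserved = profile$n_fully_conserved,
    n_paralogue_a_specific = profile$n_paralogue_a_specific,
    n_paralogue_b_specific = profile$n_paralogue_b_specific,
    single_gene_divergence = as.list(profile$single_gene_divergence),
    pairwise_similarity = as.list(profile$pairwise_similarity),
    category_counts = as.list(category_counts(profile))
  ), json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(columns = tsv, profile = json))
}
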