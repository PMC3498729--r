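#' Shared-territory and reciprocity structure of a presence matrix
#'
#' For each territory t with a non-empty expressing-gene set S(t), finds all
#' other territories t' whose gene sets contain it, i.e. every gene expressed
#' in t is also expressed in t'. A territory's row is flagged reciprocal
#' (`R`) when every such superset territory has exactly the same gene set —
#' so the sharing runs in both directions for all partners — and
#' non-reciprocal (`NR`) otherwise (a territory contained in no other is
#' vacuously `R`). Pairwise reciprocity (which individual
#' partners have equal sets) is reported separately in `reciprocal_with`.
#' Territories with no expressing gene are excluded from the rows (their
#' containment in everything is vacuous) and listed in `excluded`.
#'
#' @param matrix Binary (0/1) gene-by-territory matrix with dimnames; genes
#'   as rows.
#' @return A `territory_sharing_report`: list with
#'   \describe{
#'     \item{rows}{named list over expressing territories, each a list with
#'       `shared_with` (territory ids in column order), `reciprocal_with`
#'       (the subset of `shared_with` with exactly equal gene sets), and
#'       `reciprocal` (`"R"`/`"NR"`).}
#'     \item{excluded}{territory ids with empty gene sets.}
#'   }
#' @export
#' @examples
#' m <- rbind(g1 = c(t1 = 1, t2 = 1, t3 = 0),
#'            g2 = c(t1 = 0, t2 = 1, t3 = 0))
#' shared_territories(m)
shared_territories <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L || ncol(matrix) < 1L) {
    pd_validation_error("presence matrix must have at least one gene and one territory")
  }
  if (!all(matrix %in% c(0L, 1L))) {
    pd_validation_error("presence matrix entries must be 0 or 1")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    pd_validation_error("presence matrix must carry gene and territory names")
  }
  terr <- colnames(matrix)
  sets <- lapply(terr, function(t) rownames(matrix)[matrix[, t] == 1L])
  names(sets) <- terr
  empty <- terr[lengths(sets) == 0L]
  rows <- list()
  for (t in setdiff(terr, empty)) {
    contains <- vapply(terr, function(u) {
      u != t && all(sets[[t]] %in% sets[[u]])
    }, logical(1))
    shared <- terr[contains]
    equal <- shared[vapply(shared, function(u) setequal(sets[[u]], sets[[t]]),
                           logical(1))]
    rows[[t]] <- list(
      shared_with = shared,
      reciprocal_with = equal,
      reciprocal = if (length(equal) == length(shared)) "R" else "NR")
  }
  structure(list(rows = rows, excluded = empty, gene_sets = sets),
            class = "territory_sharing_report")
}

#' @export
print.territory_sharing_report <- function(x, ...) {
  cat(sprintf("Territory sharing report: %d expressing, %d empty territories\n",
              length(x$rows), length(x$excluded)))
  for (t in names(x$rows)) {
    r <- x$rows[[t]]
    cat(sprintf("  %-24s -> %-2s %s\n", t, r$reciprocal,
                if (length(r$shared_with)) paste(r$shared_with, collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Is a territory a universal superset of a territory group?
#'
#' Checks whether every gene expressed in any territory of `group` is also
#' expressed in `target` — e.g. whether expression anywhere in the CNS is
#' always accompanied by expression in the mesencephalon. Vacuously true when
#' no gene is expressed in the group.
#'
#' @param matrix Binary gene-by-territory matrix with dimnames.
#' @param group Character vector of territory ids (non-empty).
#' @param target Single territory id.
#' @return Logical scalar.
#' @export
universal_superset_check <- function(matrix, group, target) {
  if (!length(group)) pd_validation_error("`group` must name at least one territory")
  unknown <- setdiff(c(group, target), colnames(matrix))
  if (length(unknown)) {
    pd_validation_error(sprintf("unknown territory id(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  in_group <- rowSums(matrix[, group, drop = FALSE]) > 0
  all(matrix[in_group, target] == 1L)
}

#' Write a territory sharing report to disk
#'
#' Emits a human-readable TSV (territory, R/NR flag, shared territories) and
#' the full report, including pairwise reciprocity detail, as JSON.
#'
#' @param report A `territory_sharing_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sharing_report <- function(report, dir) {
  stopifnot(inherits(report, "territory_sharing_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "territory_sharing.tsv")
  json <- file.path(dir, "territory_sharing.json")
  df <- data.frame(
    territory = names(report$rows),
    reciprocal = vapply(report$rows, `[[`, character(1), "reciprocal"),
    shared_with = vapply(report$rows, function(r)
      paste(r$shared_with, collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rows = report$rows, excluded = report$excluded),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(table = tsv, report = json))
}
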