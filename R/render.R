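#' Render a comparison result as a symbol grid
#'
#' One row per territory and one column per comparison kind, using the
#' literal grade symbols `=`, `*`, `**`, `***` and `.` for not-applicable
#' cells, so text output is directly comparable with published
#' paralogue/orthologue comparison tables. The rendering is lossless:
#' [parse_grade_grid()] recovers the grid exactly.
#'
#' @param result A `comparison_result` from [compare_subfamily()].
#' @return Character vector of tab-separated lines (header first). An empty
#'   grid yields the header only, with a warning.
#' @export
render_grade_grid <- function(result) {
  stopifnot(inherits(result, "comparison_result"))
  kinds <- comparison_kinds()
  header <- paste(c("territory", kinds), collapse = "\t")
  terr <- unique(result$grid$territory_id)
  if (!length(terr)) {
    rlang::warn(sprintf("subfamily '%s': no territory with expression; empty grid",
                        result$subfamily))
    return(header)
  }
  rows <- vapply(terr, function(t) {
    g <- result$grid[result$grid$territory_id == t, ]
    paste(c(t, grade_symbol(g$grade[match(kinds, g$comparison)])),
          collapse = "\t")
  }, character(1))
  c(header, unname(rows))
}

#' Parse a rendered symbol grid back into a grade grid
#'
#' Inverse of [render_grade_grid()].
#'
#' @param lines Character vector of lines as produced by
#'   [render_grade_grid()].
#' @return Long data frame with `territory_id`, `comparison`, `grade`.
#' @export
parse_grade_grid <- function(lines) {
  if (!length(lines)) pd_validation_error("empty grid text")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  kinds <- fields[[1]][-1]
  if (fields[[1]][1] != "territory" || !all(kinds %in% comparison_kinds())) {
    pd_validation_error("unrecognized grade-grid header")
  }
  sym_to_grade <- setNames(names(GRADE_SYMBOLS), GRADE_SYMBOLS)
  body <- fields[-1]
  if (!length(body)) {
    return(data.frame(territory_id = character(0), comparison = character(0),
                      grade = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(body, function(f) {
    if (length(f) != length(kinds) + 1L) {
      pd_validation_error("malformed grade-grid row")
    }
    g <- sym_to_grade[f[-1]]
    if (anyNA(g)) pd_validation_error("unrecognized grade symbol in grid")
    data.frame(territory_id = f[1], comparison = kinds, grade = unname(g),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write a comparison result to disk
#'
#' Emits the symbol grid as TSV and the full result (grid, gene pairs,
#' divergence indices) as JSON.
#'
#' @param result A `comparison_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(result, dir) {
  stopifnot(inherits(result, "comparison_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, sprintf("%s_grid.tsv", result$subfamily))
  json <- file.path(dir, sprintf("%s_comparison.json", result$subfamily))
  writeLines(render_grade_grid(result), tsv)
  jsonlite::write_json(list(
    subfamily = result$subfamily,
    species = result$species,
    aggregation = result$aggregation,
    pairs = result$pairs,
    grid = result$grid,
    divergence_index = as.list(result$divergence_index)
  ), json, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(c(grid = tsv, comparison = json))
}
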