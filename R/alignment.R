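#' Construct a subfamily alignment
#'
#' A subfamily alignment holds five aligned protein sequences: the single
#' outgroup orthologue plus the "a" and "b" paralogues of two vertebrate
#' species, all the same length. Residues are uppercased on construction.
#'
#' @param sequences Named character vector of aligned sequences; names are the
#'   five role codes of [seq_roles()] (order free).
#' @param subfamily Subfamily name, e.g. `"Wnt5"`.
#' @param labels Optional named character vector mapping role codes to the
#'   original sequence labels (defaults to the role codes themselves).
#' @return A `subfamily_alignment` object: list with `subfamily`, `labels`,
#'   and `residues` (a 5 x L character matrix with roles as rownames).
#' @export
#' @examples
#' aln <- subfamily_alignment(
#'   c(outgroup = "CKGT-A", s1a = "CKGNLA", s1b = "CKSNLA",
#'     s2a = "CKGNLA", s2b = "CRSNLV"),
#'   subfamily = "toy")
#' aln
subfamily_alignment <- function(sequences, subfamily = "subfamily", labels = NULL) {
  roles <- seq_roles()
  if (!is.character(sequences) || is.null(names(sequences))) {
    pd_validation_error("`sequences` must be a named character vector")
  }
  missing <- setdiff(roles, names(sequences))
  extra <- setdiff(names(sequences), roles)
  if (length(missing) || length(extra)) {
    pd_validation_error(sprintf(
      "alignment must carry exactly the five roles %s (missing: %s; unexpected: %s)",
      paste(roles, collapse = ", "),
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"))
  }
  sequences <- toupper(sequences[roles])
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    pd_validation_error("aligned sequences must all have equal length")
  }
  if (lens[1] < 1L) pd_validation_error("alignment must have at least one column")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- roles
  check_residues(as.vector(mat))
  all_gap <- which(colSums(mat == GAP) == nrow(mat))
  if (length(all_gap)) {
    pd_validation_error(sprintf("column(s) %s are all-gap",
                                paste(all_gap, collapse = ", ")))
  }
  if (is.null(labels)) labels <- setNames(roles, roles)
  structure(list(subfamily = subfamily, labels = labels[roles], residues = mat),
            class = "subfamily_alignment")
}

#' @export
print.subfamily_alignment <- function(x, ...) {
  cat(sprintf("Subfamily alignment '%s': 5 sequences x %d columns\n",
              x$subfamily, ncol(x$residues)))
  seqs <- apply(x$residues, 1, paste, collapse = "")
  show <- substr(seqs, 1, 60)
  trunc <- ifelse(nchar(seqs) > 60, "...", "")
  for (r in seq_roles()) {
    cat(sprintf("  %-8s (%s): %s%s\n", r, x$labels[[r]], show[[r]], trunc[[r]]))
  }
  invisible(x)
}

#' Number of columns of a subfamily alignment
#'
#' @param aln A [subfamily_alignment()].
#' @return Integer alignment length.
#' @export
alignment_length <- function(aln) ncol(aln$residues)

#' Read a subfamily alignment from aligned FASTA plus a role map
#'
#' The FASTA file holds the five aligned sequences (gap character `-`); the
#' role map binds each sequence label to one of the five roles. The role map
#' may be given as a TSV file with columns `role` and `label`, or directly as
#' a named character vector `c(role = label, ...)`.
#'
#' @param fasta Path to an aligned FASTA file.
#' @param roles Path to a role-map TSV, or a named character vector.
#' @param subfamily Subfamily name recorded in the result; defaults to the
#'   FASTA file name without extension.
#' @return A [subfamily_alignment()].
#' @export
read_subfamily_alignment <- function(fasta, roles, subfamily = NULL) {
  if (!file.exists(fasta)) pd_io_error(sprintf("alignment file not found: %s", fasta))
  aa <- Biostrings::readAAStringSet(fasta)
  seqs <- setNames(as.character(aa), names(aa))
  # FASTA headers may carry descriptions after the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  role_map <- if (is.character(roles) && !is.null(names(roles))) {
    roles
  } else {
    if (!file.exists(roles)) pd_io_error(sprintf("role map not found: %s", roles))
    tab <- read.delim(roles, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("role", "label") %in% names(tab))) {
      pd_validation_error("role map must have columns 'role' and 'label'")
    }
    setNames(tab$label, tab$role)
  }
  missing_labels <- setdiff(role_map, names(seqs))
  if (length(missing_labels)) {
    pd_io_error(sprintf("role map labels not present in FASTA: %s",
                        paste(missing_labels, collapse = ", ")))
  }
  sequences <- setNames(seqs[role_map], names(role_map))
  if (is.null(subfamily)) {
    subfamily <- sub("\\.[^.]*$", "", basename(fasta))
  }
  subfamily_alignment(sequences, subfamily = subfamily,
                      labels = setNames(role_map, names(role_map)))
}

#' Write a subfamily alignment as aligned FASTA plus a role-map TSV
#'
#' Emits exactly the two files [read_subfamily_alignment()] consumes.
#'
#' @param aln A [subfamily_alignment()].
#' @param fasta,roles Output paths.
#' @return Invisibly, the two paths.
#' @export
write_subfamily_alignment <- function(aln, fasta, roles = NULL) {
  stopifnot(inherits(aln, "subfamily_alignment"))
  seqs <- apply(aln$residues, 1, paste, collapse = "")
  labels <- aln$labels
  lines <- as.vector(rbind(paste0(">", labels), seqs))
  writeLines(lines, fasta)
  if (!is.null(roles)) {
    write.table(data.frame(role = names(labels), label = unname(labels)),
                roles, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta, roles = roles))
}
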