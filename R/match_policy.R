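#' Sequence roles in a subfamily alignment
#'
#' An outgroup-anchored subfamily alignment always carries exactly five
#' sequences: the single pre-duplication outgroup gene (amphioxus, in the Wnt
#' instantiation) and the "a" and "b" paralogues of two vertebrate species
#' (chick and mouse). Roles are identified by fixed codes rather than by
#' sequence labels so that the classifier is independent of naming
#' conventions.
#'
#' @return Character vector of the five role codes, in canonical order:
#'   `"outgroup"`, `"s1a"`, `"s1b"`, `"s2a"`, `"s2b"`.
#' @export
#' @examples
#' seq_roles()
seq_roles <- function() {
  c("outgroup", "s1a", "s1b", "s2a", "s2b")
}

vertebrate_roles <- function() seq_roles()[-1L]

#' Column conservation categories
#'
#' The categories into which each alignment column is classified:
#' \describe{
#'   \item{conserved_cys}{all five residues are cysteine — the structurally
#'     invariant cysteines characteristic of Wnt ligands.}
#'   \item{fully_conserved}{all four vertebrate residues match the outgroup.}
#'   \item{single_gene_divergent}{exactly one vertebrate gene differs from an
#'     otherwise conserved site.}
#'   \item{paralogue_a_conserved, paralogue_b_conserved}{both "a" (or both
#'     "b") paralogues match the outgroup while the other pair does not —
#'     paralogue-specific conservation of the ancestral residue.}
#'   \item{vertebrate_only}{all four vertebrate residues agree with each other
#'     but none matches the outgroup.}
#'   \item{outgroup_gap}{the outgroup has a gap; the column is excluded from
#'     conservation accounting.}
#'   \item{unclassified}{any other configuration.}
#' }
#'
#' @return Character vector of the eight category codes.
#' @export
column_categories <- function() {
  c("conserved_cys", "fully_conserved", "single_gene_divergent",
    "paralogue_a_conserved", "paralogue_b_conserved", "vertebrate_only",
    "outgroup_gap", "unclassified")
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"

#' Default physicochemical similarity groups
#'
#' The "strong" amino-acid groups used by classic progressive aligners to
#' call conservative substitutions. Used by [match_policy()] in `"groups"`
#' mode: two distinct residues match if they fall in the same group.
#'
#' @return Named list of character vectors; groups are pairwise disjoint.
#' @export
similarity_groups <- function() {
  list(
    STA  = c("S", "T", "A"),
    NEQK = c("N", "E", "Q", "K"),
    MILV = c("M", "I", "L", "V"),
    HY   = c("H", "Y"),
    FW   = c("F", "W"),
    DG   = c("D", "G"),
    RC   = c("R"),
    P    = c("P")
  )
}

#' Residue matching policy
#'
#' Defines what "conserved" means when a vertebrate residue is compared with
#' the outgroup residue. `"identity"` requires the same amino acid letter;
#' `"groups"` additionally accepts residues from the same physicochemical
#' group (conservative substitutions), which is how percent *similarity*
#' rather than percent identity is conventionally computed.
#'
#' @param mode `"identity"` (default) or `"groups"`.
#' @param groups List of disjoint character vectors of amino-acid letters;
#'   only consulted in `"groups"` mode. Defaults to [similarity_groups()].
#' @return A `match_policy` object.
#' @export
#' @examples
#' p <- match_policy("groups")
#' residues_match("I", "L", p)  # conservative substitution
#' residues_match("I", "L", match_policy("identity"))
match_policy <- function(mode = c("identity", "groups"), groups = similarity_groups()) {
  mode <- match.arg(mode)
  stopifnot(is.list(groups))
  letters_seen <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(letters_seen)) {
    pd_validation_error("similarity groups must be pairwise disjoint")
  }
  if (!all(letters_seen %in% AA_LETTERS)) {
    pd_validation_error("similarity groups may only contain amino-acid letters")
  }
  group_of <- rep(names(groups), lengths(groups))
  names(group_of) <- letters_seen
  structure(list(mode = mode, groups = groups, group_of = group_of),
            class = "match_policy")
}

#' Do two residues match under a policy?
#'
#' Gaps never match anything, including another gap.
#'
#' @param a,b Single residue characters (amino-acid letter or `"-"`).
#' @param policy A [match_policy()].
#' @return Logical scalar.
#' @export
residues_match <- function(a, b, policy) {
  if (a == GAP || b == GAP) return(FALSE)
  if (a == b) return(TRUE)
  if (policy$mode == "identity") return(FALSE)
  ga <- policy$group_of[a]
  gb <- policy$group_of[b]
  !is.na(ga) && !is.na(gb) && ga == gb
}

check_residues <- function(x, what = "residue") {
  bad <- setdiff(unique(x), c(AA_LETTERS, GAP))
  if (length(bad)) {
    pd_validation_error(sprintf("illegal %s character(s): %s", what,
                                paste(bad, collapse = ", ")))
  }
  invisible(x)
}
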