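#' Synthetic Wnt gene-by-territory presence matrix
#'
#' A hand-constructed, fully synthetic illustration of the sharing structure
#' typical of vertebrate Wnt expression surveys: eight gene labels across
#' twenty embryonic territories, built so that (i) every gene expressed
#' anywhere in the CNS is also expressed in the mesencephalon, (ii)
#' branchial arches 1 and 2 carry identical gene sets, as do arches 3 and 4
#' (and the posterior pair's set is nested in the anterior pair's), and
#' (iii) the limb-ectoderm and lung gene sets are nested in several cranial
#' territories. It does not reproduce any published matrix cell-for-cell; it
#' exists so the subset/reciprocity machinery can be exercised on a matrix
#' with realistic nesting.
#'
#' @return Binary integer matrix, 8 genes x 20 territories, territory
#'   columns in [default_territory_vocabulary()] order (without the `cns`
#'   grouping entry).
#' @export
#' @examples
#' m <- synthetic_wnt_presence()
#' shared_territories(m)
synthetic_wnt_presence <- function() {
  genes <- c("Wnt2", "Wnt2b", "Wnt5a", "Wnt5b", "Wnt7a", "Wnt7b",
             "Wnt8a", "Wnt8b")
  vocab <- default_territory_vocabulary()
  terr <- vocab$id[vocab$id != "cns"]
  sets <- list(
    telencephalon       = c("Wnt2b", "Wnt7a", "Wnt7b"),
    diencephalon        = c("Wnt2b", "Wnt5a", "Wnt5b", "Wnt7a", "Wnt7b"),
    mesencephalon       = genes,
    rhombencephalon     = c("Wnt5a", "Wnt7a", "Wnt7b"),
    neural_tube         = c("Wnt5a", "Wnt5b", "Wnt7a", "Wnt7b"),
    eye                 = c("Wnt5a", "Wnt5b", "Wnt7b", "Wnt8b"),
    otic_vesicle        = c("Wnt7b", "Wnt8b"),
    frontonasal_process = c("Wnt5a", "Wnt5b", "Wnt7b"),
    branchial_arch_1    = c("Wnt2b", "Wnt5a", "Wnt5b", "Wnt7a", "Wnt7b"),
    branchial_arch_2    = c("Wnt2b", "Wnt5a", "Wnt5b", "Wnt7a", "Wnt7b"),
    branchial_arch_3    = c("Wnt5a", "Wnt7b"),
    branchial_arch_4    = c("Wnt5a", "Wnt7b"),
    limb_ectoderm       = c("Wnt5a", "Wnt5b", "Wnt7a"),
    limb_mesenchyme     = c("Wnt2", "Wnt2b", "Wnt5a"),
    somites             = c("Wnt5a", "Wnt5b"),
    heart               = c("Wnt2", "Wnt2b", "Wnt8b"),
    lung                = c("Wnt5b", "Wnt7b"),
    gut                 = c("Wnt2b", "Wnt5a", "Wnt5b", "Wnt7b"),
    genitourinary       = c("Wnt2", "Wnt5a", "Wnt7b"),
    tail_bud            = c("Wnt5a", "Wnt8a")
  )
  m <- matrix(0L, nrow = length(genes), ncol = length(terr),
              dimnames = list(genes, terr))
  for (t in names(sets)) m[sets[[t]], t] <- 1L
  m
}

#' CNS territory ids of the default vocabulary
#'
#' The territory ids grouped under the CNS in
#' [default_territory_vocabulary()].
#'
#' @return Character vector of territory ids.
#' @export
cns_territories <- function() {
  vocab <- default_territory_vocabulary()
  vocab$id[!is.na(vocab$parent_id) & vocab$parent_id == "cns"]
}
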