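#' Simulate a functional gene-set collection from annotations
#'
#' Term-derived sets are the propagated annotated-gene lists of randomly
#' chosen terms (a term's set contains every gene annotated to it or to any
#' descendant); optional extra sets are drawn at random from the annotated
#' genes. Seeded draws are reproducible.
#'
#' @param annotations Annotation tibble.
#' @param onto A [ontology()] object.
#' @param n_sets Number of term-derived sets.
#' @param min_size Smallest eligible propagated term size.
#' @param max_size Largest eligible propagated term size (`Inf` to disable;
#'   the default skips namespace roots and near-root terms).
#' @param n_random Number of additional random sets.
#' @param random_size_range Size range of the random sets.
#' @param seed Optional seed.
#' @return Collection tibble (see [as_collection()]) with sources
#'   `"ontology"` and `"random"`.
#' @export
sim_genesets <- function(annotations, onto, n_sets = 20, min_size = 6,
                         max_size = NULL, n_random = 0,
                         random_size_range = c(10, 30), seed = NULL) {
  check_scalar_number(n_sets, "n_sets", lower = 0)
  prop <- propagate_annotations(onto, annotations)
  genes_by_term <- split(prop$gene_id, prop$term_id)
  genes_by_term <- lapply(genes_by_term, unique)
  n_universe <- length(unique(annotations$gene_id))
  max_size <- max_size %||% ceiling(0.5 * n_universe)
  sizes <- lengths(genes_by_term)
  eligible <- names(genes_by_term)[sizes >= min_size & sizes <= max_size &
                                     !(names(genes_by_term) %in% onto$roots)]
  if (length(eligible) < n_sets) {
    abort(sprintf("only %d terms have between %d and %d propagated genes; cannot draw %d sets.",
                  length(eligible), min_size, as.integer(max_size), n_sets))
  }
  with_seed(seed, {
    chosen <- sample(eligible, n_sets)
    coll <- tibble(set_name = chosen,
                   source = "ontology",
                   genes = genes_by_term[chosen])
    if (n_random > 0) {
      universe <- unique(annotations$gene_id)
      rnd <- lapply(seq_len(n_random), function(i) {
        sample(universe, sample(random_size_range[1]:random_size_range[2], 1L))
      })
      coll <- bind_rows(coll, tibble(
        set_name = sprintf("random_%03d", seq_len(n_random)),
        source = "random", genes = rnd))
    }
    as_collection(coll)
  })
}
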