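#' Simulate an ontology and gene annotations with tunable pair similarity
#'
#' Builds one rooted DAG per namespace by layered random attachment (each
#' term picks 1-2 parents from the previous layer, which guarantees
#' acyclicity and a unique root) and annotates every gene with a handful of
#' non-root terms. For each planted pair, the `pair_similarity` probability
#' `q` of its namespace is the exact chance the two members share at least
#' one non-root term: with probability `q` a shared term is planted into both
#' term sets, otherwise the second member's terms are resampled until
#' disjoint from the first's. Random (unplanted) gene pairs share terms only
#' by chance, at a rate set by the annotation density.
#'
#' @param gene_ids Character vector of genes to annotate (e.g.
#'   `sim_genome()$genes$gene_id`).
#' @param pairs Planted-pair tibble (`minus_gene`, `plus_gene`), or an empty
#'   tibble.
#' @param n_terms_per_namespace Terms per namespace, including the root.
#' @param max_depth Number of layers below the root.
#' @param branching Mean children per term; shapes the layer sizes.
#' @param annotations_per_gene Two-element range; each gene receives a
#'   uniform draw of that many direct annotations.
#' @param pair_similarity Named probabilities `q` per namespace.
#' @param seed Optional seed.
#' @return List with `ontology` (a [ontology()] object) and `annotations`
#'   (tibble: `gene_id`, `term_id`, `evidence`).
#' @export
sim_ontology <- function(gene_ids, pairs = NULL,
                         n_terms_per_namespace = 95,
                         max_depth = 5,
                         branching = 3,
                         annotations_per_gene = c(2, 4),
                         pair_similarity = c(BP = 0.1, CC = 0.9, MF = 0.6),
                         seed = NULL) {
  check_scalar_number(n_terms_per_namespace, "n_terms_per_namespace", lower = 2)
  check_scalar_number(max_depth, "max_depth", lower = 1)
  if (any(pair_similarity < 0 | pair_similarity > 1)) {
    abort("`pair_similarity` values must lie in [0, 1].")
  }
  namespaces <- names(pair_similarity)
  with_seed(seed, {
    terms <- list()
    parents <- list()
    for (ns in namespaces) {
      built <- build_random_dag(ns, n_terms_per_namespace, max_depth, branching)
      terms[[ns]] <- built$terms
      parents <- c(parents, built$parents)
    }
    onto <- ontology(bind_rows(terms), parents)

    k_range <- annotations_per_gene
    ann <- list()
    for (ns in namespaces) {
      ns_terms <- onto$terms$term_id[onto$terms$namespace == ns]
      non_root <- setdiff(ns_terms, onto$roots[[ns]])
      k <- sample(k_range[1]:k_range[2], length(gene_ids), replace = TRUE)
      sets <- lapply(k, function(ki) sample(non_root, min(ki, length(non_root))))
      names(sets) <- gene_ids
      q <- pair_similarity[[ns]]
      if (!is.null(pairs) && nrow(pairs) > 0L) {
        share <- runif(nrow(pairs)) < q
        for (i in seq_len(nrow(pairs))) {
          g1 <- pairs$minus_gene[i]
          g2 <- pairs$plus_gene[i]
          if (share[i]) {
            t <- sample(non_root, 1L)
            sets[[g1]][1L] <- t
            sets[[g2]][1L] <- t
          } else {
            # force disjoint term sets
            for (attempt in 1:100) {
              if (length(intersect(sets[[g1]], sets[[g2]])) == 0L) break
              sets[[g2]] <- sample(non_root, length(sets[[g2]]))
            }
          }
          sets[[g1]] <- unique(sets[[g1]])
          sets[[g2]] <- unique(sets[[g2]])
        }
      }
      sets <- lapply(sets, unique)
      ann[[ns]] <- tibble(gene_id = rep(names(sets), lengths(sets)),
                          term_id = unlist(sets, use.names = FALSE))
    }
    annotations <- bind_rows(ann)
    annotations$evidence <- sample(c("EXP", "IDA", "IMP", "ISS", "IEA"),
                                   nrow(annotations), replace = TRUE,
                                   prob = c(0.15, 0.2, 0.15, 0.2, 0.3))
    list(ontology = onto, annotations = annotations)
  })
}

build_random_dag <- function(ns, n_terms, max_depth, branching) {
  root <- sprintf("%s:%04d", ns, 1L)
  n_rest <- n_terms - 1L
  # geometric layer sizes proportional to branching^depth
  wt <- branching^seq_len(max_depth)
  sizes <- floor(wt / sum(wt) * n_rest)
  rem <- n_rest - sum(sizes)
  if (rem > 0) {
    sizes[max_depth] <- sizes[max_depth] + rem
  }
  sizes <- sizes[sizes > 0]
  if (length(sizes) == 0L && n_rest > 0L) {
    sizes <- n_rest
  }
  ids <- sprintf("%s:%04d", ns, seq_len(n_terms))
  parents <- list()
  parents[[root]] <- character()
  prev_layer <- root
  k <- 1L
  for (sz in sizes) {
    layer <- ids[k + seq_len(sz)]
    k <- k + sz
    for (t in layer) {
      n_par <- min(sample(1:2, 1L), length(prev_layer))
      parents[[t]] <- sample(prev_layer, n_par)
    }
    prev_layer <- layer
  }
  list(terms = tibble(term_id = ids,
                      name = paste0("term ", ids),
                      namespace = ns),
       parents = parents)
}
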