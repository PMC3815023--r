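#' Construct an ontology DAG
#'
#' A lightweight rooted DAG per namespace, holding `is_a` parent links only.
#' The constructor validates acyclicity, a unique root per namespace, and that
#' every non-root term reaches its namespace root; ancestor sets (including
#' the term itself) are precomputed and stored.
#'
#' @param terms Tibble with columns `term_id`, `name`, `namespace`.
#' @param parents Named list mapping `term_id` to a character vector of
#'   parent term ids (empty for roots).
#' @return An object of class `dpg_ontology` with elements `terms`,
#'   `parents`, `roots` (named by namespace) and `ancestors`.
#' @export
ontology <- function(terms, parents) {
  terms <- as_tibble(terms)
  stopifnot(all(c("term_id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$term_id)) {
    abort("duplicate term ids.")
  }
  parents <- parents[terms$term_id]
  names(parents) <- terms$term_id
  parents <- lapply(parents, function(p) as.character(p %||% character()))
  bad <- setdiff(unlist(parents), terms$term_id)
  if (length(bad) > 0L) {
    abort(paste0("parent terms not present in `terms`: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  ns_of <- setNames(terms$namespace, terms$term_id)
  for (id in terms$term_id) {
    if (any(ns_of[parents[[id]]] != ns_of[[id]])) {
      abort("is_a links must stay within one namespace.")
    }
  }
  order <- topo_order(terms$term_id, parents)           # errors on cycles
  roots <- terms$term_id[lengths(parents) == 0L]
  root_ns <- terms$namespace[match(roots, terms$term_id)]
  if (anyDuplicated(root_ns) || !setequal(root_ns, unique(terms$namespace))) {
    abort("each namespace must have exactly one root term.")
  }
  anc <- vector("list", nrow(terms))
  names(anc) <- terms$term_id
  for (id in order) {                                    # parents before children
    anc[[id]] <- unique(c(id, unlist(anc[parents[[id]]], use.names = FALSE)))
  }
  structure(list(terms = terms, parents = parents,
                 roots = setNames(roots, root_ns), ancestors = anc),
            class = "dpg_ontology")
}

# Kahn topological order (parents first); errors on cycles.
topo_order <- function(ids, parents) {
  remaining <- setNames(lengths(parents), ids)
  children <- split(rep(names(parents), lengths(parents)),
                    unlist(parents, use.names = FALSE))
  queue <- ids[remaining == 0L]
  out <- character(length(ids))
  k <- 0L
  while (length(queue) > 0L) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    k <- k + 1L
    out[k] <- id
    for (ch in children[[id]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) {
        queue <- c(queue, ch)
      }
    }
  }
  if (k != length(ids)) {
    abort("ontology graph contains a cycle.")
  }
  out
}

#' @export
print.dpg_ontology <- function(x, ...) {
  ns <- table(x$terms$namespace)
  cat("<dpg_ontology> ", nrow(x$terms), " terms in ",
      length(ns), " namespace(s): ",
      paste(sprintf("%s (%d)", names(ns), ns), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ancestor set of a term (including the term itself)
#'
#' @param onto A [ontology()] object.
#' @param term_id Term identifier.
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(onto, term_id) {
  a <- onto$ancestors[[term_id]]
  if (is.null(a)) {
    abort(sprintf("unknown term `%s`.", term_id))
  }
  a
}

term_namespace <- function(onto, term_id) {
  onto$terms$namespace[match(term_id, onto$terms$term_id)]
}

#' Filter an annotation corpus
#'
#' Annotation tables have columns `gene_id`, `term_id`, `evidence`. Electronic
#' annotations (IEA) are kept by default; they can be
#' dropped, and terms unknown to the ontology are rejected.
#'
#' @param annotations Annotation tibble.
#' @param onto A [ontology()] object.
#' @param include_iea Keep IEA-evidence assignments?
#' @return The filtered annotation tibble with a `namespace` column added.
#' @export
filter_annotations <- function(annotations, onto, include_iea = TRUE) {
  annotations <- as_tibble(annotations)
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  if (!"evidence" %in% names(annotations)) {
    annotations$evidence <- "EXP"
  }
  bad <- setdiff(annotations$term_id, onto$terms$term_id)
  if (length(bad) > 0L) {
    abort(paste0("annotations reference unknown terms: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (!include_iea) {
    annotations <- annotations[annotations$evidence != "IEA", ]
  }
  annotations$namespace <- term_namespace(onto, annotations$term_id)
  distinct(annotations, .data$gene_id, .data$term_id, .keep_all = TRUE)
}

#' Information content of ontology terms
#'
#' For one namespace, the annotation probability of a term is the number of
#' genes annotated to the term or any of its descendants divided by the number
#' of genes annotated anywhere in the namespace; information content is the
#' negative natural log of that probability. Terms with no (propagated)
#' annotation are excluded.
#'
#' @param onto A [ontology()] object.
#' @param annotations Annotation tibble (see [filter_annotations()]).
#' @param namespace Namespace to compute the table for.
#' @return Tibble with `term_id`, `namespace`, `n_genes`, `p`, `ic`.
#' @export
build_ic <- function(onto, annotations, namespace) {
  ann <- annotations[term_namespace(onto, annotations$term_id) == namespace, ]
  if (nrow(ann) == 0L) {
    abort(sprintf("no annotations in namespace `%s`.", namespace))
  }
  prop <- propagate_annotations(onto, ann)
  n_total <- length(unique(ann$gene_id))
  counts <- prop |>
    distinct(.data$gene_id, .data$term_id) |>
    count(.data$term_id, name = "n_genes")
  tibble(term_id = counts$term_id,
         namespace = namespace,
         n_genes = counts$n_genes,
         p = counts$n_genes / n_total,
         ic = -log(counts$n_genes / n_total))
}

# Expand (gene, term) assignments to all ancestors of the term.
propagate_annotations <- function(onto, annotations) {
  anc <- onto$ancestors[annotations$term_id]
  tibble(gene_id = rep(annotations$gene_id, lengths(anc)),
         term_id = unlist(anc, use.names = FALSE)) |>
    distinct()
}

#' Direct annotations per gene, as a named list
#'
#' Root-only annotated genes are treated as unannotated for similarity, so the
#' namespace root is dropped before collecting term sets.
#'
#' @inheritParams build_ic
#' @param drop_root Drop the namespace root from term sets?
#' @return Named list mapping gene id to a character vector of term ids.
#' @export
gene_term_sets <- function(onto, annotations, namespace, drop_root = TRUE) {
  ann <- annotations[term_namespace(onto, annotations$term_id) == namespace, ]
  if (drop_root) {
    ann <- ann[ann$term_id != onto$roots[[namespace]], ]
  }
  split(ann$term_id, ann$gene_id)
}
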