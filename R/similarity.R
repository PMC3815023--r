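#' Schlicker relevance similarity of two terms
#'
#' `max` over common ancestors `a` of
#' `2 * IC(a) / (IC(t1) + IC(t2)) * (1 - p(a))`: a Lin-style IC ratio
#' down-weighted by the annotation probability of the most informative common
#' ancestor, which corrects the shallow-annotation problem (two terms whose
#' only shared ancestor is near the root score near 0 even when the IC ratio
#' is 1). Defined as 0 when `IC(t1) + IC(t2) = 0`.
#'
#' @param t1,t2 Term ids in the same namespace, both present in `ic`.
#' @param ic IC table from [build_ic()].
#' @param onto A [ontology()] object.
#' @return Similarity in `[0, 1]`.
#' @export
term_similarity_rel <- function(t1, t2, ic, onto) {
  if (!identical(term_namespace(onto, t1), term_namespace(onto, t2))) {
    abort("terms must belong to the same namespace.")
  }
  idx <- match(c(t1, t2), ic$term_id)
  if (anyNA(idx)) {
    abort("both terms must have a defined information content.")
  }
  denom <- sum(ic$ic[idx])
  if (denom == 0) {
    return(0)
  }
  common <- intersect(term_ancestors(onto, t1), term_ancestors(onto, t2))
  common <- common[common %in% ic$term_id]
  if (length(common) == 0L) {
    return(0)
  }
  ia <- match(common, ic$term_id)
  max(2 * ic$ic[ia] / denom * (1 - ic$p[ia]))
}

# Full term-by-term relevance-similarity matrix for one namespace.
# Since sim(t1,t2) = 2/(IC1+IC2) * max over common ancestors of IC(a)(1-p(a)),
# the inner max is computed once per ancestor by sweeping its descendant set.
namespace_sim_matrix <- function(ic, onto) {
  ids <- ic$term_id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids)) # A[t, a]: a ancestor of t
  for (i in seq_len(n)) {
    a <- intersect(term_ancestors(onto, ids[i]), ids)
    A[i, match(a, ids)] <- TRUE
  }
  w <- ic$ic * (1 - ic$p)
  M <- matrix(0, n, n)
  for (k in order(w)) { # ascending: later (larger) weights overwrite
    if (w[k] <= 0) next
    d <- which(A[, k])
    M[d, d] <- w[k]
  }
  denom <- outer(ic$ic, ic$ic, "+")
  S <- ifelse(denom > 0, 2 * M / denom, 0)
  dimnames(S) <- list(ids, ids)
  S
}

#' Combine a term-set similarity matrix by rcmax.avg
#'
#' Returns `(sum of row maxima + sum of column maxima) / (n_rows + n_cols)`.
#'
#' @param sim_matrix Numeric matrix of pairwise term similarities in `[0, 1]`.
#' @return A single score, or `NA` for an empty matrix (undefined similarity).
#' @examples
#' combine_rcmax_avg(matrix(c(0.8, 0.4, 0.2, 0.6), 2)) # 0.7
#' @export
combine_rcmax_avg <- function(sim_matrix) {
  if (is.null(dim(sim_matrix)) || any(dim(sim_matrix) == 0L)) {
    return(NA_real_)
  }
  if (any(sim_matrix < 0 | sim_matrix > 1)) {
    abort("similarity entries must lie in [0, 1].")
  }
  rm <- apply(sim_matrix, 1L, max)
  cm <- apply(sim_matrix, 2L, max)
  (sum(rm) + sum(cm)) / (nrow(sim_matrix) + ncol(sim_matrix))
}

#' Semantic similarity of a gene pair in one namespace
#'
#' Builds the pairwise term-similarity matrix from the two genes' direct
#' annotations (root-only annotations dropped) and combines it with
#' [combine_rcmax_avg()]. Returns `NA` (undefined) when either gene has no
#' usable annotation in the namespace; undefined pairs are excluded from
#' downstream distributions, never scored 0.
#'
#' @param g1,g2 Gene ids.
#' @param annotations Annotation tibble.
#' @param ic IC table from [build_ic()].
#' @param onto A [ontology()] object.
#' @param namespace Namespace to score in.
#' @return Similarity in `[0, 1]`, or `NA`.
#' @export
gene_pair_similarity <- function(g1, g2, annotations, ic, onto, namespace) {
  sets <- gene_term_sets(onto, annotations, namespace)
  S <- namespace_sim_matrix(ic, onto)
  pair_score(sets[[g1]], sets[[g2]], S)
}

pair_score <- function(t1, t2, S) {
  t1 <- intersect(t1, rownames(S))
  t2 <- intersect(t2, rownames(S))
  n1 <- length(t1)
  n2 <- length(t2)
  if (n1 == 0L || n2 == 0L) {
    return(NA_real_)
  }
  sub <- S[t1, t2, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) / (n1 + n2)
}

#' Score many gene pairs at once
#'
#' Vectorised driver used for DPG-vs-background comparisons: the full
#' term-similarity matrix for the namespace is computed once and reused.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` (or `minus_gene`,
#'   `plus_gene`).
#' @inheritParams gene_pair_similarity
#' @return The input tibble with a `score` column (`NA` where undefined).
#' @export
pair_similarity_table <- function(pairs, annotations, ic, onto, namespace) {
  pairs <- as_tibble(pairs)
  if (all(c("minus_gene", "plus_gene") %in% names(pairs))) {
    ga <- pairs$minus_gene
    gb <- pairs$plus_gene
  } else {
    ga <- pairs$gene_a
    gb <- pairs$gene_b
  }
  sets <- gene_term_sets(onto, annotations, namespace)
  S <- namespace_sim_matrix(ic, onto)
  idx <- setNames(seq_len(nrow(S)), rownames(S))
  set_idx <- lapply(sets, function(t) unname(idx[t[t %in% names(idx)]]))
  score1 <- function(a, b) {
    i1 <- set_idx[[a]]
    i2 <- set_idx[[b]]
    n1 <- length(i1)
    n2 <- length(i2)
    if (n1 == 0L || is.null(i1) || n2 == 0L || is.null(i2)) {
      return(NA_real_)
    }
    sub <- S[i1, i2, drop = FALSE]
    (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) / (n1 + n2)
  }
  pairs$score <- vapply(seq_along(ga), function(i) score1(ga[i], gb[i]), numeric(1))
  pairs
}

#' Sample random background gene pairs
#'
#' Uniform unordered pairs of distinct genes, sampled with replacement across
#' pairs. The published analysis used 100,000 background pairs.
#'
#' @param genes Character vector of eligible gene ids (at least 2).
#' @param n_pairs Number of pairs to draw (default 100,000).
#' @param seed Optional seed for reproducibility.
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
sample_background <- function(genes, n_pairs = 100000, seed = NULL) {
  if (length(unique(genes)) < 2L) {
    abort("need at least 2 distinct genes to sample pairs.")
  }
  check_scalar_number(n_pairs, "n_pairs", lower = 1)
  genes <- unique(genes)
  with_seed(seed, {
    a <- sample(genes, n_pairs, replace = TRUE)
    b <- sample(genes, n_pairs, replace = TRUE)
    while (any(same <- a == b)) {
      b[same] <- sample(genes, sum(same), replace = TRUE)
    }
    tibble(gene_a = pmin(a, b), gene_b = pmax(a, b))
  })
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The statistic is the supremum distance between the two empirical CDFs; the
#' p-value uses the asymptotic Kolmogorov distribution (adequate at the
#' hundreds-to-thousands sample sizes this package works at).
#'
#' @param x,y Non-empty numeric vectors (NAs dropped).
#' @return Tibble with columns `ks_D` and `ks_p`.
#' @export
compare_ks <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort("both samples must be non-empty.")
  }
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  tibble(ks_D = unname(kt$statistic), ks_p = min(kt$p.value, 1))
}

#' Compare DPG similarity scores to a random-pair background
#'
#' For each namespace, runs the two-sample KS test of the defined (non-`NA`)
#' DPG scores against the defined background scores and records means and the
#' shift direction.
#'
#' @param dpg_scores,background_scores Tibbles with columns `namespace` and
#'   `score` (e.g. stacked outputs of [pair_similarity_table()]).
#' @return Object of class `dpg_sim_compare`; see [tidy.dpg_sim_compare()].
#' @export
compare_pair_similarity <- function(dpg_scores, background_scores) {
  namespaces <- sort(unique(dpg_scores$namespace))
  rows <- lapply(namespaces, function(ns) {
    d <- dpg_scores$score[dpg_scores$namespace == ns]
    b <- background_scores$score[background_scores$namespace == ns]
    du <- sum(is.na(d))
    bu <- sum(is.na(b))
    d <- d[!is.na(d)]
    b <- b[!is.na(b)]
    ks <- compare_ks(d, b)
    tibble(namespace = ns,
           n_dpg = length(d), n_dpg_undefined = du,
           n_background = length(b), n_background_undefined = bu,
           dpg_mean = mean(d), background_mean = mean(b),
           shift = ifelse(mean(d) > mean(b), "right", "left"),
           ks_D = ks$ks_D, ks_p = ks$ks_p)
  })
  structure(list(summary = bind_rows(rows),
                 dpg_scores = as_tibble(dpg_scores),
                 background_scores = as_tibble(background_scores)),
            class = "dpg_sim_compare")
}

#' @export
print.dpg_sim_compare <- function(x, ...) {
  cat("<dpg_sim_compare> DPG vs random-pair GO similarity\n")
  print(x$summary)
  invisible(x)
}

#' Drop same-family (paralog-like) pairs
#'
#' Removes pairs whose two members carry the same family label (e.g. the
#' histone gene pairs that dominate the high-similarity peak). Genes without
#' a family label never match.
#'
#' @param pairs Pair tibble (`minus_gene`/`plus_gene` or `gene_a`/`gene_b`).
#' @param families Named character vector or two-column data frame
#'   (`gene_id`, `family`) mapping genes to family labels.
#' @return The filtered pair tibble.
#' @export
exclude_paralog_pairs <- function(pairs, families) {
  if (is.data.frame(families)) {
    families <- setNames(as.character(families$family), families$gene_id)
  }
  if (length(families) == 0L) {
    return(pairs)
  }
  cols <- if ("minus_gene" %in% names(pairs)) {
    c("minus_gene", "plus_gene")
  } else {
    c("gene_a", "gene_b")
  }
  fa <- unname(families[pairs[[cols[1]]]])
  fb <- unname(families[pairs[[cols[2]]]])
  same <- !is.na(fa) & !is.na(fb) & fa == fb
  pairs[!same, ]
}

#' Hypergeometric term enrichment
#'
#' For every propagated term annotated to at least `min_term_size` background
#' genes, the upper-tail hypergeometric probability of the observed study-set
#' overlap, with Benjamini-Hochberg adjustment across tested terms.
#'
#' @param study_genes Character vector, subset of `background_genes`.
#' @param background_genes Character vector of universe gene ids.
#' @param annotations Annotation tibble.
#' @param onto A [ontology()] object.
#' @param min_term_size Smallest background annotation count tested.
#' @return Tibble with `term_id`, `namespace`, `n_background`, `n_study`,
#'   `p_value`, `p_adjusted`, sorted by p-value.
#' @export
term_enrichment <- function(study_genes, background_genes, annotations, onto,
                            min_term_size = 3) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (length(study_genes) == 0L) {
    abort("`study_genes` must be non-empty.")
  }
  if (!all(study_genes %in% background_genes)) {
    abort("`study_genes` must be a subset of `background_genes`.")
  }
  ann <- annotations[annotations$gene_id %in% background_genes, ]
  prop <- propagate_annotations(onto, ann)
  by_term <- split(prop$gene_id, prop$term_id)
  by_term <- by_term[lengths(by_term) >= min_term_size]
  if (length(by_term) == 0L) {
    return(tibble(term_id = character(), namespace = character(),
                  n_background = integer(), n_study = integer(),
                  p_value = numeric(), p_adjusted = numeric()))
  }
  N <- length(background_genes)
  n <- length(study_genes)
  K <- lengths(by_term)
  k <- vapply(by_term, function(g) sum(g %in% study_genes), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(term_id = names(by_term),
                namespace = term_namespace(onto, names(by_term)),
                n_background = unname(K), n_study = unname(k),
                p_value = unname(p),
                p_adjusted = p.adjust(unname(p), method = "BH"))
  arrange(out, .data$p_value, .data$term_id)
}
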