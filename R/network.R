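#' Functional gene-set collections
#'
#' A collection is a tibble with columns `set_name`, `source` (free label such
#' as "pathway", "ontology", "disease") and a list-column `genes` of character
#' vectors. `as_collection()` builds one from a named list.
#'
#' @param sets Named list of character vectors, or a collection tibble.
#' @param source Source label recycled over sets.
#' @return Collection tibble.
#' @export
as_collection <- function(sets, source = "set") {
  if (is.data.frame(sets)) {
    sets <- as_tibble(sets)
    stopifnot(all(c("set_name", "genes") %in% names(sets)))
    if (!"source" %in% names(sets)) {
      sets$source <- source
    }
    sets$genes <- unname(lapply(sets$genes, function(g) unique(as.character(g))))
    return(sets[, c("set_name", "source", "genes")])
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.")
  }
  tibble(set_name = names(sets), source = source,
         genes = unname(lapply(sets, function(g) unique(as.character(g)))))
}

collection_list <- function(collection) {
  setNames(collection$genes, collection$set_name)
}

#' Overlap rate of two gene sets
#'
#' The Simpson coefficient: `|A intersect B| / min(|A|, |B|)`.
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @return Proportion in `[0, 1]`.
#' @export
overlap_rate <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("sets must be non-empty.")
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Interaction rate of two gene sets bridged by DPG pairs
#'
#' A DPG pair bridges sets A and B when one member lies in `A \ B` and the
#' other in `B \ A` (pairs falling inside the intersection do not count).
#' The rate normalises the bridging-pair count by the smaller set size, the
#' same convention as [overlap_rate()]; a geometric-mean denominator is
#' available for sensitivity checks.
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @param pairs Pair tibble with `minus_gene`, `plus_gene`.
#' @param denominator `"min"` (default) or `"geometric"`.
#' @return List with `n_bridging` and `rate`.
#' @export
interaction_rate <- function(a, b, pairs, denominator = c("min", "geometric")) {
  denominator <- match.arg(denominator)
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("sets must be non-empty.")
  }
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  m <- pairs$minus_gene
  p <- pairs$plus_gene
  bridges <- (m %in% only_a & p %in% only_b) | (m %in% only_b & p %in% only_a)
  denom <- switch(denominator,
                  min = min(length(a), length(b)),
                  geometric = sqrt(length(a) * length(b)))
  list(n_bridging = sum(bridges), rate = sum(bridges) / denom,
       bridging = which(bridges))
}

#' Filter a collection by size and mutual overlap
#'
#' Keeps sets with more than `min_size - 1` members and, scanning sets
#' greedily in descending size order (ties by name), drops any set whose
#' overlap rate with an already-retained set reaches `max_overlap`. The
#' published filter used size > 5 and overlap < 80%.
#'
#' @param collection Collection tibble.
#' @param min_size Smallest retained size (default 6, i.e. size > 5).
#' @param max_overlap Overlap-rate bound (strictly below; default 0.8).
#' @return The filtered collection tibble.
#' @export
filter_categories <- function(collection, min_size = 6, max_overlap = 0.8) {
  collection <- as_collection(collection)
  sizes <- lengths(collection$genes)
  collection <- collection[sizes >= min_size, ]
  if (nrow(collection) == 0L) {
    return(collection)
  }
  ord <- order(-lengths(collection$genes), collection$set_name)
  collection <- collection[ord, ]
  kept <- integer()
  for (i in seq_len(nrow(collection))) {
    g <- collection$genes[[i]]
    ok <- TRUE
    for (j in kept) {
      if (overlap_rate(g, collection$genes[[j]]) >= max_overlap) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      kept <- c(kept, i)
    }
  }
  collection[kept, ]
}

#' Build the overlap or interaction map of a set collection
#'
#' Computes pairwise overlap and interaction statistics for every pair of
#' sets and keeps edges whose rate of the chosen kind strictly exceeds the
#' cutoff (published defaults: interaction rate > 0.07, overlap rate > 0.30).
#' Coverage statistics count the distinct DPG genes appearing in bridging
#' pairs of retained edges, relative to the DPG genes annotated anywhere in
#' the collection.
#'
#' @param collection Collection tibble (normally pre-filtered with
#'   [filter_categories()]).
#' @param pairs DPG pair tibble from [find_dpgs()].
#' @param map_kind `"interaction"` or `"overlap"`.
#' @param cutoff Strict lower bound for retained edges; defaults to 0.07
#'   (interaction) or 0.30 (overlap).
#' @param denominator Interaction-rate denominator, see [interaction_rate()].
#' @return Object of class `dpg_set_network` with elements `nodes`, `edges`,
#'   `map_kind`, `cutoff`, `coverage`.
#' @export
build_set_network <- function(collection, pairs,
                              map_kind = c("interaction", "overlap"),
                              cutoff = NULL,
                              denominator = "min") {
  map_kind <- match.arg(map_kind)
  cutoff <- cutoff %||% switch(map_kind, interaction = 0.07, overlap = 0.30)
  check_scalar_number(cutoff, "cutoff", lower = 0)
  collection <- as_collection(collection)
  sets <- collection_list(collection)
  nm <- names(sets)
  nodes <- tibble(set_name = nm, size = lengths(sets),
                  source = collection$source)
  edges <- list()
  if (length(sets) >= 2L) {
    combo <- utils::combn(seq_along(sets), 2L)
    rows <- lapply(seq_len(ncol(combo)), function(k) {
      i <- combo[1L, k]
      j <- combo[2L, k]
      ov <- length(intersect(sets[[i]], sets[[j]]))
      ir <- interaction_rate(sets[[i]], sets[[j]], pairs,
                             denominator = denominator)
      tibble(set_a = nm[i], set_b = nm[j],
             n_overlap_genes = ov,
             overlap_rate = ov / min(length(sets[[i]]), length(sets[[j]])),
             n_bridging = ir$n_bridging,
             interaction_rate = ir$rate,
             bridging_pairs = list(pairs[ir$bridging, , drop = FALSE]))
    })
    edges <- bind_rows(rows)
  } else {
    edges <- tibble(set_a = character(), set_b = character(),
                    n_overlap_genes = integer(), overlap_rate = numeric(),
                    n_bridging = integer(), interaction_rate = numeric(),
                    bridging_pairs = list())
  }
  rate_col <- if (map_kind == "interaction") "interaction_rate" else "overlap_rate"
  edges <- edges[edges[[rate_col]] > cutoff, ]
  edges$weight <- edges[[rate_col]]
  dpg_in_collection <- intersect(dpg_genes(pairs), unique(unlist(sets)))
  dpg_in_edges <- unique(unlist(lapply(edges$bridging_pairs, dpg_genes)))
  connected <- unique(c(edges$set_a, edges$set_b))
  coverage <- list(
    n_sets = length(sets),
    n_sets_connected = length(connected),
    n_dpg_annotated = length(dpg_in_collection),
    n_dpg_in_edges = length(dpg_in_edges),
    relative_coverage_pct = relative_coverage(length(dpg_in_edges),
                                              length(dpg_in_collection))
  )
  structure(list(nodes = nodes, edges = as_tibble(edges), map_kind = map_kind,
                 cutoff = cutoff, denominator = denominator,
                 coverage = coverage),
            class = "dpg_set_network")
}

#' @export
print.dpg_set_network <- function(x, ...) {
  cat(sprintf("<dpg_set_network> %s map: %d sets, %d edges (rate > %g)\n",
              x$map_kind, nrow(x$nodes), nrow(x$edges), x$cutoff))
  cat(sprintf("  DPG coverage: %d of %d annotated DPG genes (%.2f%%)\n",
              x$coverage$n_dpg_in_edges, x$coverage$n_dpg_annotated,
              x$coverage$relative_coverage_pct))
  invisible(x)
}

#' Relative DPG coverage, in percent
#'
#' `100 * n_covered / n_annotated`, the coverage statistic reported for the
#' interaction map (e.g. 1,262 of 1,359 annotated DPGs = 92.86%).
#'
#' @param n_covered,n_annotated Counts.
#' @return Percentage (0 when nothing is annotated).
#' @export
relative_coverage <- function(n_covered, n_annotated) {
  if (n_annotated == 0) {
    return(0)
  }
  100 * n_covered / n_annotated
}

#' DPG fraction of each category
#'
#' Percentage of each set's members that are DPG genes (the published
#' report style: e.g. 6 of 13 genes = 46.15%).
#'
#' @param collection Collection tibble.
#' @param dpg_gene_ids Character vector of DPG member gene ids.
#' @return Tibble with `set_name`, `size`, `n_dpg`, `dpg_pct`.
#' @export
dpg_set_fractions <- function(collection, dpg_gene_ids) {
  collection <- as_collection(collection)
  tibble(set_name = collection$set_name,
         size = unname(lengths(collection$genes)),
         n_dpg = unname(vapply(collection$genes,
                               function(g) sum(g %in% dpg_gene_ids),
                               integer(1)))) |>
    mutate(dpg_pct = 100 * .data$n_dpg / .data$size)
}

network_weight_matrix <- function(network) {
  nm <- network$nodes$set_name
  W <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(network$edges) > 0L) {
    ia <- match(network$edges$set_a, nm)
    ib <- match(network$edges$set_b, nm)
    W[cbind(ia, ib)] <- network$edges$weight
    W[cbind(ib, ia)] <- network$edges$weight
  }
  W
}

#' Cohesiveness of a node group
#'
#' `f(V) = w_in / (w_in + w_bound + penalty * |V|)`, where `w_in` is the total
#' weight of edges with both endpoints in `V` and `w_bound` the total weight
#' of edges with exactly one endpoint in `V`. Edge weight is the network's
#' retained rate (interaction or overlap). The penalty models unreliable or
#' missing edges; 2 is the conventional default.
#'
#' @param network A [build_set_network()] object.
#' @param members Character vector of node names (non-empty).
#' @param penalty Per-node penalty term.
#' @return Cohesiveness in `[0, 1]`.
#' @export
cohesiveness <- function(network, members, penalty = 2) {
  W <- network_weight_matrix(network)
  if (length(members) == 0L || !all(members %in% rownames(W))) {
    abort("`members` must be a non-empty subset of the network's nodes.")
  }
  inside <- rownames(W) %in% members
  w_in <- sum(W[inside, inside, drop = FALSE]) / 2
  w_bound <- sum(W[inside, !inside, drop = FALSE])
  denom <- w_in + w_bound + penalty * sum(inside)
  if (denom == 0) 0 else w_in / denom
}

cohesiveness_w <- function(W, inside, penalty) {
  w_in <- sum(W[inside, inside, drop = FALSE]) / 2
  w_bound <- sum(W[inside, !inside, drop = FALSE])
  denom <- w_in + w_bound + penalty * sum(inside)
  if (denom == 0) 0 else w_in / denom
}

#' Detect modules by greedy cohesiveness growth
#'
#' A ClusterONE-style procedure: groups are grown greedily from seeds in
#' decreasing weighted-degree order, adding or removing one node at a time
#' while cohesiveness strictly increases; growth is multi-pass (new seeds are
#' taken from still-uncovered nodes until every node is covered or no seed
#' grows). Grown groups whose pairwise Simpson coefficient
#' `|A intersect B| / min(|A|, |B|)` reaches `merge_threshold` are merged
#' transitively; groups below `min_size` are dropped. Each module gets a
#' one-sided Mann-Whitney p-value comparing its internal edge weights against
#' its boundary edge weights (`NA` when it has no boundary edges).
#'
#' @param network A [build_set_network()] object with at least one edge.
#' @param penalty Cohesiveness penalty, see [cohesiveness()].
#' @param merge_threshold Simpson coefficient at or above which groups merge.
#' @param min_size Smallest reported module size.
#' @return Object of class `dpg_modules`: a tibble with `module`, `members`
#'   (list-column), `n_sets`, `cohesiveness`, `p_value`.
#' @export
cluster_modules <- function(network, penalty = 2, merge_threshold = 0.8,
                            min_size = 3) {
  W <- network_weight_matrix(network)
  nm <- rownames(W)
  if (nrow(network$edges) == 0L) {
    return(new_modules(tibble(module = integer(), members = list(),
                              n_sets = integer(), cohesiveness = numeric(),
                              p_value = numeric()),
                       penalty, merge_threshold, min_size))
  }
  wdeg <- rowSums(W)
  covered <- rep(FALSE, length(nm))
  groups <- list()
  for (s in order(-wdeg, nm)) {
    if (covered[s] || wdeg[s] == 0) next
    inside <- rep(FALSE, length(nm))
    inside[s] <- TRUE
    f <- cohesiveness_w(W, inside, penalty)
    repeat {
      # candidate moves: add an outside neighbour, or remove a member
      nbr <- which(!inside & colSums(W[inside, , drop = FALSE] > 0) > 0)
      mem <- which(inside)
      cand <- c(nbr, if (sum(inside) > 1L) mem)
      if (length(cand) == 0L) break
      gains <- vapply(cand, function(v) {
        ins <- inside
        ins[v] <- !ins[v]
        cohesiveness_w(W, ins, penalty)
      }, numeric(1))
      best <- which(gains > f + 1e-12)
      if (length(best) == 0L) break
      pick <- best[order(-gains[best], nm[cand[best]])][1L]
      v <- cand[pick]
      inside[v] <- !inside[v]
      f <- gains[pick]
    }
    groups[[length(groups) + 1L]] <- nm[inside]
    covered[inside] <- TRUE
  }
  if (length(groups) == 0L) {
    return(new_modules(tibble(module = integer(), members = list(),
                              n_sets = integer(), cohesiveness = numeric(),
                              p_value = numeric()),
                       penalty, merge_threshold, min_size))
  }
  groups <- unique(groups)
  groups <- merge_groups(groups, merge_threshold)
  groups <- groups[lengths(groups) >= min_size]
  rows <- lapply(groups, function(g) {
    inside <- nm %in% g
    tibble(members = list(sort(g)), n_sets = length(g),
           cohesiveness = cohesiveness_w(W, inside, penalty),
           p_value = module_p_value(W, inside))
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0L) {
    out <- out[order(-out$n_sets, vapply(out$members, `[`, character(1), 1L)), ]
    out <- mutate(out, module = row_number())
    out <- out[, c("module", "members", "n_sets", "cohesiveness", "p_value")]
  }
  new_modules(out, penalty, merge_threshold, min_size)
}

new_modules <- function(tbl, penalty, merge_threshold, min_size) {
  structure(tbl, class = c("dpg_modules", class(tbl)),
            penalty = penalty, merge_threshold = merge_threshold,
            min_size = min_size)
}

# Transitive merging of groups with Simpson coefficient >= threshold:
# connected components of the pairwise-overlap graph, each unioned.
merge_groups <- function(groups, threshold) {
  n <- length(groups)
  if (n <= 1L) {
    return(groups)
  }
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      simpson <- length(intersect(groups[[i]], groups[[j]])) /
        min(length(groups[[i]]), length(groups[[j]]))
      if (simpson >= threshold) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  unname(lapply(split(seq_len(n), comp),
                function(idx) Reduce(union, groups[idx])))
}

# One-sided Mann-Whitney: are internal edge weights larger than boundary ones?
module_p_value <- function(W, inside) {
  Wi <- W[inside, inside, drop = FALSE]
  internal <- Wi[upper.tri(Wi)]
  internal <- internal[internal > 0]
  boundary <- as.vector(W[inside, !inside, drop = FALSE])
  boundary <- boundary[boundary > 0]
  if (length(internal) == 0L || length(boundary) == 0L) {
    return(NA_real_)
  }
  suppressWarnings(
    wilcox.test(internal, boundary, alternative = "greater",
                exact = length(internal) < 50 && length(boundary) < 50)$p.value
  )
}

#' @export
print.dpg_modules <- function(x, ...) {
  cat(sprintf("<dpg_modules> %d module(s), penalty %g\n",
              nrow(x), attr(x, "penalty")))
  NextMethod()
}
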