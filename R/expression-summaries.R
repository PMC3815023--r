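sample_tissues <- function(expr) {
  if ("tissue" %in% names(expr$samples)) {
    expr$samples$tissue
  } else {
    expr$samples$group
  }
}

#' Quartile-mean absolute correlation of DPG pairs, by group
#'
#' For every pair, the Pearson correlation of the two members' expression
#' across all samples; per group, the mean of the three quartiles of the
#' absolute correlations. Pairs with a constant profile (zero variance) are
#' skipped and counted.
#'
#' @param expr A [expression_data()] object.
#' @param pair_groups Named list of pair tibbles (`minus_gene`, `plus_gene`),
#'   e.g. from [pair_groups_from_network()].
#' @param quartile_type Quantile convention.
#' @return Tibble with `group`, `n_pairs`, `n_skipped`, `mean_abs_r`
#'   (quartile mean of `|r|`).
#' @export
pair_correlation_summary <- function(expr, pair_groups, quartile_type = 7) {
  vals <- expr$values
  rows <- lapply(names(pair_groups), function(lab) {
    pr <- pair_groups[[lab]]
    keep <- pr$minus_gene %in% rownames(vals) & pr$plus_gene %in% rownames(vals)
    pr <- pr[keep, ]
    r <- vapply(seq_len(nrow(pr)), function(i) {
      x <- vals[pr$minus_gene[i], ]
      y <- vals[pr$plus_gene[i], ]
      if (sd(x) == 0 || sd(y) == 0) {
        return(NA_real_)
      }
      cor(x, y)
    }, numeric(1))
    skipped <- sum(is.na(r)) + sum(!keep)
    r <- r[!is.na(r)]
    tibble(group = lab, n_pairs = length(r), n_skipped = skipped,
           mean_abs_r = if (length(r) > 0) quartile_mean(abs(r), quartile_type)
                        else NA_real_)
  })
  bind_rows(rows)
}

#' Pair groups at increasing interaction-rate cutoffs
#'
#' Builds the comparison groups used for the pair-correlation figure:
#' `inter<c>` holds the DPG pairs bridging at least one edge with interaction
#' rate above cutoff `c` (default cutoffs 0.07, 0.08, 0.1, 0.2), `other` the
#' pairs excluded by the loosest cutoff, and `module<k>` the pairs bridging
#' edges inside each detected module.
#'
#' @param network A [build_set_network()] interaction map (its edge table
#'   must contain all edges above the loosest cutoff requested).
#' @param pairs DPG pair tibble.
#' @param cutoffs Increasing interaction-rate cutoffs.
#' @param modules Optional [cluster_modules()] result.
#' @return Named list of pair tibbles.
#' @export
pair_groups_from_network <- function(network, pairs,
                                     cutoffs = c(0.07, 0.08, 0.1, 0.2),
                                     modules = NULL) {
  edges <- network$edges
  pair_key <- function(p) paste(p$minus_gene, p$plus_gene)
  bridging_keys <- function(ed) {
    unique(unlist(lapply(ed$bridging_pairs, pair_key)))
  }
  groups <- list()
  for (cc in cutoffs) {
    keys <- bridging_keys(edges[edges$interaction_rate > cc, ])
    groups[[sprintf("inter%g", cc)]] <- pairs[pair_key(pairs) %in% keys, ]
  }
  base_keys <- bridging_keys(edges[edges$interaction_rate > min(cutoffs), ])
  groups[["other"]] <- pairs[!(pair_key(pairs) %in% base_keys), ]
  if (!is.null(modules) && nrow(modules) > 0L) {
    for (i in seq_len(nrow(modules))) {
      mem <- modules$members[[i]]
      ed <- edges[edges$set_a %in% mem & edges$set_b %in% mem, ]
      keys <- bridging_keys(ed)
      groups[[sprintf("module%d", modules$module[i])]] <-
        pairs[pair_key(pairs) %in% keys, ]
    }
  }
  groups
}

#' Between-tissue expression variance per gene
#'
#' Variance over the per-tissue mean expression values (one mean per tissue),
#' the convention used for the tissue-variance maps.
#'
#' @param expr A [expression_data()] object whose sample sheet has a
#'   `tissue` column (or whose `group` labels are tissues).
#' @return Tibble with `gene_id`, `tissue_variance`.
#' @export
gene_tissue_variance <- function(expr) {
  tissues <- sample_tissues(expr)
  if (length(unique(tissues)) < 2L) {
    abort("need at least 2 tissues.")
  }
  means <- tissue_means(expr$values, tissues)
  tibble(gene_id = rownames(means),
         tissue_variance = apply(means, 1L, var))
}

tissue_means <- function(values, tissues) {
  out <- vapply(split(seq_along(tissues), tissues),
                function(i) rowMeans(values[, i, drop = FALSE]),
                numeric(nrow(values)))
  rownames(out) <- rownames(values)
  out
}

#' Tissue-variance summary and bin per functional set
#'
#' Per set, the quartile mean of its measured members' between-tissue
#' variances, binned as on the published variance maps: below 0.4 is
#' below-threshold, 0.4-0.5 low (green), 0.5-0.7 mid (yellow), above 0.7
#' high (red).
#'
#' @param expr A [expression_data()] object with >= 3 tissues.
#' @param collection Collection tibble.
#' @param members_of Optional gene universe to intersect members with (e.g.
#'   DPG genes).
#' @param quartile_type Quantile convention.
#' @return Tibble with `set_name`, `n_members_measured`, `variance`, `bin`.
#' @export
tissue_variance_bins <- function(expr, collection, members_of = NULL,
                                 quartile_type = 7) {
  tissues <- sample_tissues(expr)
  if (length(unique(tissues)) < 3L) {
    abort("need at least 3 tissues.")
  }
  gv <- gene_tissue_variance(expr)
  v <- setNames(gv$tissue_variance, gv$gene_id)
  collection <- as_collection(collection)
  rows <- lapply(seq_len(nrow(collection)), function(i) {
    g <- collection$genes[[i]]
    if (!is.null(members_of)) {
      g <- intersect(g, members_of)
    }
    g <- intersect(g, names(v))
    val <- if (length(g) > 0) quartile_mean(v[g], quartile_type) else NA_real_
    tibble(set_name = collection$set_name[i],
           n_members_measured = length(g), variance = val)
  })
  out <- bind_rows(rows)
  out$bin <- variance_bin(out$variance)
  out
}

variance_bin <- function(v) {
  dplyr::case_when(
    is.na(v) ~ NA_character_,
    v < 0.4 ~ "below_threshold",
    v <= 0.5 ~ "low",
    v <= 0.7 ~ "mid",
    TRUE ~ "high"
  )
}

#' Call housekeeping genes from multi-tissue expression
#'
#' A gene is called housekeeping when its per-tissue mean expression exceeds
#' the presence threshold in every tissue and its between-tissue variance
#' stays below the cap. Defaults: threshold = overall matrix median,
#' cap = 0.5 on the log2 scale.
#'
#' @param expr A [expression_data()] object with >= 2 tissues.
#' @param presence_threshold Expression every tissue mean must exceed;
#'   `NULL` uses the matrix median.
#' @param variance_cap Upper bound (strict) on between-tissue variance.
#' @return Character vector of housekeeping gene ids.
#' @export
call_housekeeping <- function(expr, presence_threshold = NULL,
                              variance_cap = 0.5) {
  tissues <- sample_tissues(expr)
  if (length(unique(tissues)) < 2L) {
    abort("need at least 2 tissues.")
  }
  presence_threshold <- presence_threshold %||% median(expr$values)
  means <- tissue_means(expr$values, tissues)
  present <- apply(means, 1L, function(x) all(x > presence_threshold))
  stable <- apply(means, 1L, var) < variance_cap
  rownames(expr$values)[present & stable]
}

#' Overlap statistics of gene lists against the DPG gene list
#'
#' Per list: its overlap with the DPG genes as a count and as a fraction of
#' the list. Across lists: the intersection and union sizes, and of the
#' union's DPG genes, how many are organised as complete DPG pairs (both
#' members present).
#'
#' @param lists Named list of gene-id vectors (e.g. housekeeping-gene lists
#'   from several studies).
#' @param pairs DPG pair tibble.
#' @return List with elements `per_list` (tibble: `list`, `n`, `n_dpg`,
#'   `dpg_fraction`), `intersection_size`, `union_size`, `n_union_dpg`,
#'   `n_complete_pairs`, `n_in_complete_pairs`.
#' @export
list_overlap_stats <- function(lists, pairs) {
  if (length(lists) == 0L) {
    abort("`lists` must contain at least one gene list.")
  }
  lists <- lapply(lists, unique)
  dg <- dpg_genes(pairs)
  per_list <- bind_rows(lapply(names(lists), function(nm) {
    g <- lists[[nm]]
    tibble(list = nm, n = length(g), n_dpg = length(intersect(g, dg)),
           dpg_fraction = length(intersect(g, dg)) / length(g))
  }))
  inter <- Reduce(intersect, lists)
  uni <- Reduce(union, lists)
  union_dpg <- intersect(uni, dg)
  complete <- pairs$minus_gene %in% union_dpg & pairs$plus_gene %in% union_dpg
  list(per_list = per_list,
       intersection_size = length(inter),
       union_size = length(uni),
       n_union_dpg = length(union_dpg),
       n_complete_pairs = sum(complete),
       n_in_complete_pairs = 2L * sum(complete))
}
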