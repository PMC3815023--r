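#' Simulate a log2 expression matrix with planted effects
#'
#' Values are `baseline + gene effect + group effect + noise` on the log2
#' scale. Three kinds of structure can be planted:
#'
#' * **Differential expression**: genes in `planted_de_sets` are shifted by
#'   the stated log2 fold change in the case group(s); DPG members of those
#'   sets receive `dpg_extra` (default `planted_dpg_extra_shift`) on top.
#' * **Uniform (non-differential) shifts**: genes in `uniform_shift_sets`
#'   are shifted equally in every group, so they carry expression change but
#'   no case/control differential.
#' * **Tissue profiles** (when groups represent tissues): a
#'   `housekeeping_fraction` of genes is expressed above baseline in every
#'   group with very low between-group variability; a
#'   `tissue_specific_fraction` is high in one or two groups and low
#'   elsewhere; the remainder wanders moderately between groups.
#'
#' @param gene_ids Character vector of gene ids.
#' @param groups Tibble with `label`, `n_samples` (every group >= 2 samples).
#' @param case_groups Labels of the groups that receive the planted
#'   differential shifts.
#' @param collection Optional collection the planted set names refer to.
#' @param planted_de_sets Optional tibble `set_name`, `lfc` and optionally
#'   `dpg_extra`; names must exist in `collection`.
#' @param planted_dpg_extra_shift Default extra case-group shift for DPG
#'   members of planted DE sets.
#' @param pairs Optional DPG pair tibble identifying the DPG members.
#' @param uniform_shift_sets Optional tibble `set_name`, `shift` applied to
#'   all groups alike.
#' @param baseline_log_mean Grand mean of the log2 values.
#' @param gene_sd Between-gene spread of baseline expression.
#' @param noise_sd Within-group measurement noise (> 0).
#' @param group_effect_sd Between-group wander of unclassed genes; leave 0
#'   for clean case/control contrasts, set ~1 for multi-tissue profiles.
#' @param housekeeping_fraction,tissue_specific_fraction Proportions of
#'   genes given housekeeping / tissue-specific profiles.
#' @param seed Optional seed.
#' @return List with `expr` (a [expression_data()] object) and `gene_info`
#'   (tibble: `gene_id`, `class` in `none`/`housekeeping`/`tissue_specific`,
#'   `de_shift` actually applied in the case groups).
#' @export
sim_expression <- function(gene_ids,
                           groups = tibble(label = sprintf("tissue%02d", 1:10),
                                           n_samples = 3L),
                           case_groups = character(),
                           collection = NULL,
                           planted_de_sets = NULL,
                           planted_dpg_extra_shift = 0,
                           pairs = NULL,
                           uniform_shift_sets = NULL,
                           baseline_log_mean = 8,
                           gene_sd = 1,
                           noise_sd = 0.5,
                           group_effect_sd = 0,
                           housekeeping_fraction = 0,
                           tissue_specific_fraction = 0,
                           seed = NULL) {
  groups <- as_tibble(groups)
  stopifnot(all(c("label", "n_samples") %in% names(groups)))
  if (any(groups$n_samples < 2L)) {
    abort("every group needs at least 2 samples.")
  }
  if (noise_sd <= 0) {
    abort("`noise_sd` must be positive.")
  }
  if (housekeeping_fraction + tissue_specific_fraction > 1) {
    abort("class fractions must sum to at most 1.")
  }
  set_genes <- if (!is.null(collection)) collection_list(collection) else list()
  for (tbl in list(planted_de_sets, uniform_shift_sets)) {
    if (!is.null(tbl) && !all(tbl$set_name %in% names(set_genes))) {
      abort("planted set names must exist in `collection`.")
    }
  }
  n_genes <- length(gene_ids)
  n_groups <- nrow(groups)
  with_seed(seed, {
    classes <- rep("none", n_genes)
    n_hk <- round(housekeeping_fraction * n_genes)
    n_ts <- round(tissue_specific_fraction * n_genes)
    special <- sample(n_genes, n_hk + n_ts)
    classes[special[seq_len(n_hk)]] <- "housekeeping"
    classes[special[n_hk + seq_len(n_ts)]] <- "tissue_specific"

    baseline <- baseline_log_mean + rnorm(n_genes, 0, gene_sd)
    baseline[classes == "housekeeping"] <-
      baseline_log_mean + 2 + rnorm(n_hk, 0, 0.5)

    # per-gene, per-group effects
    eff <- matrix(0, n_genes, n_groups,
                  dimnames = list(gene_ids, groups$label))
    if (n_groups > 1L) {
      idx_none <- which(classes == "none")
      if (group_effect_sd > 0) {
        eff[idx_none, ] <- rnorm(length(idx_none) * n_groups, 0, group_effect_sd)
      }
      idx_hk <- which(classes == "housekeeping")
      eff[idx_hk, ] <- rnorm(length(idx_hk) * n_groups, 0, 0.1)
      for (i in which(classes == "tissue_specific")) {
        on <- sample(n_groups, sample(1:2, 1L))
        eff[i, ] <- -2.5
        eff[i, on] <- 3
      }
    }
    de_shift <- rep(0, n_genes)
    names(de_shift) <- gene_ids
    dpg_members <- if (!is.null(pairs)) dpg_genes(pairs) else character()
    if (!is.null(planted_de_sets) && nrow(planted_de_sets) > 0L) {
      if (length(case_groups) == 0L) {
        abort("`case_groups` must be given when planting differential sets.")
      }
      pd <- as_tibble(planted_de_sets)
      if (!"dpg_extra" %in% names(pd)) {
        pd$dpg_extra <- planted_dpg_extra_shift
      }
      for (i in seq_len(nrow(pd))) {
        members <- intersect(set_genes[[pd$set_name[i]]], gene_ids)
        de_shift[members] <- de_shift[members] + pd$lfc[i]
        extra <- intersect(members, dpg_members)
        de_shift[extra] <- de_shift[extra] + pd$dpg_extra[i]
      }
      case_idx <- match(case_groups, groups$label)
      if (anyNA(case_idx)) {
        abort("unknown case group label.")
      }
      eff[, case_idx] <- eff[, case_idx] + de_shift
    }
    if (!is.null(uniform_shift_sets) && nrow(uniform_shift_sets) > 0L) {
      us <- as_tibble(uniform_shift_sets)
      for (i in seq_len(nrow(us))) {
        members <- intersect(set_genes[[us$set_name[i]]], gene_ids)
        eff[members, ] <- eff[members, ] + us$shift[i]
      }
    }

    sample_group <- rep(groups$label, groups$n_samples)
    sample_ids <- paste0(sample_group, "_s",
                         unlist(lapply(groups$n_samples, seq_len)))
    vals <- baseline +
      eff[, match(sample_group, groups$label), drop = FALSE] +
      matrix(rnorm(n_genes * length(sample_ids), 0, noise_sd),
             n_genes, length(sample_ids))
    colnames(vals) <- sample_ids
    rownames(vals) <- gene_ids
    expr <- expression_data(vals, tibble(sample_id = sample_ids,
                                         group = sample_group,
                                         tissue = sample_group))
    list(expr = expr,
         gene_info = tibble(gene_id = gene_ids, class = classes,
                            de_shift = unname(de_shift)))
  })
}
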