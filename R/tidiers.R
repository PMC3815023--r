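#' Tidy the DPG-vs-background similarity comparison
#'
#' @param x A `dpg_sim_compare` object from [compare_pair_similarity()].
#' @param ... Unused.
#' @return One row per namespace with sample sizes, means, shift direction
#'   and the KS statistic and p-value.
#' @export
tidy.dpg_sim_compare <- function(x, ...) {
  x$summary
}

#' @rdname tidy.dpg_sim_compare
#' @export
glance.dpg_sim_compare <- function(x, ...) {
  tibble(n_namespaces = nrow(x$summary),
         n_dpg_pairs = max(x$summary$n_dpg + x$summary$n_dpg_undefined),
         n_background_pairs = max(x$summary$n_background +
                                    x$summary$n_background_undefined),
         min_ks_p = min(x$summary$ks_p))
}

#' Tidy a set network
#'
#' @param x A `dpg_set_network` object from [build_set_network()].
#' @param ... Unused.
#' @return The edge table (bridging pairs as a list-column).
#' @export
tidy.dpg_set_network <- function(x, ...) {
  x$edges
}

#' @rdname tidy.dpg_set_network
#' @export
glance.dpg_set_network <- function(x, ...) {
  tibble(map_kind = x$map_kind, cutoff = x$cutoff,
         n_sets = x$coverage$n_sets,
         n_sets_connected = x$coverage$n_sets_connected,
         n_edges = nrow(x$edges),
         n_dpg_annotated = x$coverage$n_dpg_annotated,
         n_dpg_in_edges = x$coverage$n_dpg_in_edges,
         relative_coverage_pct = x$coverage$relative_coverage_pct)
}

#' Tidy detected modules
#'
#' @param x A `dpg_modules` object from [cluster_modules()].
#' @param ... Unused.
#' @return One row per module with members flattened to a comma-separated
#'   string.
#' @export
tidy.dpg_modules <- function(x, ...) {
  tibble(module = x$module, n_sets = x$n_sets,
         cohesiveness = x$cohesiveness, p_value = x$p_value,
         members = vapply(x$members, paste, character(1), collapse = ","))
}

#' @rdname tidy.dpg_modules
#' @export
glance.dpg_modules <- function(x, ...) {
  tibble(n_modules = nrow(x),
         penalty = attr(x, "penalty"),
         merge_threshold = attr(x, "merge_threshold"),
         min_size = attr(x, "min_size"),
         mean_cohesiveness = if (nrow(x) > 0) mean(x$cohesiveness) else NA_real_)
}
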