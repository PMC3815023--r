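#' Run the full synthetic DPG analysis pipeline
#'
#' Orchestrates every stage on simulated inputs with known ground truth:
#' genome simulation, DPG calling, chromosome enrichment, per-namespace GO
#' similarity of DPG pairs against a sampled random-pair background,
#' gene-set construction and filtering, the DPG-bridged interaction map with
#' module detection, case/control differential expression with absolute and
#' relative pathway scores, pair-correlation summaries, and
#' housekeeping-gene calling on a multi-tissue matrix. One seed drives
#' per-stage substreams ([dpg_seeds()]), so reruns are identical and any
#' stage can be re-executed standalone from the returned inputs.
#'
#' @param seed Integer seed for the whole run.
#' @param genome Named list of [sim_genome()] overrides.
#' @param ontology_sim Named list of [sim_ontology()] overrides.
#' @param n_background Background pairs for the similarity comparison.
#' @param genesets Named list of [sim_genesets()] overrides.
#' @param expression_sim Named list of [sim_expression()] overrides for the
#'   case/control matrix (its `groups`/`case_groups` defaults are two groups
#'   of 10 samples).
#' @param tissue_sim Named list of [sim_expression()] overrides for the
#'   multi-tissue matrix.
#' @param window DPG window (bp).
#' @param interaction_cutoff Interaction-map edge cutoff.
#' @param n_perm Permutations for relative pathway scores.
#' @param outdir Optional directory; when given, stage outputs are written
#'   (BED, OBO, annotation TSV, GMT, expression TSV, pair and score TSVs,
#'   SIF/GraphML, JSON manifest).
#' @return List of stage outputs plus a `manifest` recording the
#'   configuration, seeds, per-stage row counts and decided conventions.
#' @export
run_dpg_pipeline <- function(seed = 1,
                             genome = list(n_genes = 4000, n_planted_pairs = 200,
                                           chromosome_lengths = rep(4e6, 8)),
                             ontology_sim = list(),
                             n_background = 20000,
                             genesets = list(n_sets = 30),
                             expression_sim = list(),
                             tissue_sim = list(housekeeping_fraction = 1 / 3,
                                               tissue_specific_fraction = 0.3,
                                               group_effect_sd = 1),
                             window = 1000,
                             interaction_cutoff = 0.07,
                             n_perm = 10000,
                             outdir = NULL) {
  seeds <- dpg_seeds(seed)

  sim <- do.call(sim_genome, c(genome, list(seed = seeds[["genome"]])))
  pairs <- find_dpgs(sim$genes, window = window)
  enrich <- chromosome_enrichment(sim$genes, dpg_genes(pairs))

  onto_sim <- do.call(sim_ontology,
                      c(list(gene_ids = sim$genes$gene_id, pairs = pairs),
                        ontology_sim, list(seed = seeds[["ontology"]])))
  onto <- onto_sim$ontology
  ann <- filter_annotations(onto_sim$annotations, onto)
  namespaces <- unique(onto$terms$namespace)
  bg <- sample_background(intersect(sim$genes$gene_id, unique(ann$gene_id)),
                          n_pairs = n_background,
                          seed = seeds[["background"]])
  sim_scores <- lapply(namespaces, function(ns) {
    ic <- build_ic(onto, ann, ns)
    dpg <- pair_similarity_table(pairs, ann, ic, onto, ns)
    bgs <- pair_similarity_table(bg, ann, ic, onto, ns)
    list(dpg = tibble(namespace = ns, score = dpg$score),
         bg = tibble(namespace = ns, score = bgs$score))
  })
  similarity <- compare_pair_similarity(
    bind_rows(lapply(sim_scores, `[[`, "dpg")),
    bind_rows(lapply(sim_scores, `[[`, "bg")))

  coll <- do.call(sim_genesets, c(list(annotations = ann, onto = onto),
                                  genesets, list(seed = seeds[["genesets"]])))
  coll <- filter_categories(coll)
  network <- build_set_network(coll, pairs, map_kind = "interaction",
                               cutoff = interaction_cutoff)
  modules <- cluster_modules(network)

  expr_defaults <- list(
    gene_ids = sim$genes$gene_id,
    groups = tibble(label = c("control", "case"), n_samples = 10L),
    case_groups = "case",
    collection = coll,
    planted_de_sets = if (nrow(coll) > 0) {
      tibble(set_name = coll$set_name[1], lfc = 2)
    },
    pairs = pairs)
  expr_sim <- do.call(sim_expression,
                      c(expression_sim,
                        expr_defaults[setdiff(names(expr_defaults),
                                              names(expression_sim))],
                        list(seed = seeds[["expression"]])))
  de <- moderated_de(expr_sim$expr, case = "case", control = "control")
  scores <- score_pathways(coll, de, members_of = dpg_genes(pairs),
                           n_perm = n_perm, seed = seeds[["permutation"]])
  corr <- pair_correlation_summary(
    expr_sim$expr,
    pair_groups_from_network(network, pairs, modules = modules))

  tissue_defaults <- list(gene_ids = sim$genes$gene_id)
  tissue <- do.call(sim_expression,
                    c(tissue_sim,
                      tissue_defaults[setdiff(names(tissue_defaults),
                                              names(tissue_sim))],
                      list(seed = seeds[["expression"]] + 1L)))
  hkg <- call_housekeeping(tissue$expr)
  hkg_stats <- list_overlap_stats(list(simulated = hkg), pairs)
  tvar <- tissue_variance_bins(tissue$expr, coll)

  manifest <- list(
    seed = seed, seeds = as.list(seeds),
    window = window, interaction_cutoff = interaction_cutoff,
    n_perm = n_perm, n_background = n_background,
    conventions = list(coordinates = "0-based half-open; TSS = start (+) / end-1 (-)",
                       quartiles = "type 7 (linear interpolation)",
                       interaction_rate_denominator = network$denominator,
                       log_base_ic = "natural", score = "-log10(p)"),
    counts = list(n_genes = nrow(sim$genes), n_dpg_pairs = nrow(pairs),
                  n_planted_pairs = nrow(sim$truth),
                  n_terms = nrow(onto$terms), n_annotations = nrow(ann),
                  n_sets = nrow(coll), n_edges = nrow(network$edges),
                  n_modules = nrow(modules), n_hkg = length(hkg)))
  out <- list(genome = sim, pairs = pairs, chromosome_enrichment = enrich,
              ontology = onto, annotations = ann, similarity = similarity,
              collection = coll, network = network, modules = modules,
              expression = expr_sim, de = de, pathway_scores = scores,
              pair_correlations = corr, tissue_expression = tissue,
              housekeeping = hkg, hkg_overlap = hkg_stats,
              tissue_variance = tvar, manifest = manifest)
  if (!is.null(outdir)) {
    write_pipeline_outputs(out, outdir)
  }
  out
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_gene_table(out$genome$genes, fp("genes.bed"))
  write_json_report(out$genome$truth, fp("planted_pairs.json"))
  readr::write_tsv(out$pairs, fp("dpg_pairs.tsv"), progress = FALSE)
  readr::write_tsv(out$chromosome_enrichment, fp("chromosome_enrichment.tsv"),
                   progress = FALSE)
  write_obo(out$ontology, fp("ontology.obo"))
  write_annotations(out$annotations, fp("annotations.tsv"))
  readr::write_tsv(out$similarity$summary, fp("similarity_summary.tsv"),
                   progress = FALSE)
  write_gmt(out$collection, fp("sets.gmt"))
  write_network_sif(out$network, fp("network.sif"))
  write_network_graphml(out$network, fp("network.graphml"))
  readr::write_tsv(tidy(out$modules), fp("modules.tsv"), progress = FALSE)
  write_expression(out$expression$expr, fp("expression.tsv"))
  readr::write_tsv(out$de, fp("differential_expression.tsv"), progress = FALSE)
  readr::write_tsv(out$pathway_scores, fp("pathway_scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(out$pair_correlations, fp("pair_correlations.tsv"),
                   progress = FALSE)
  writeLines(out$housekeeping, fp("housekeeping_genes.txt"))
  readr::write_tsv(out$tissue_variance, fp("tissue_variance.tsv"),
                   progress = FALSE)
  write_json_report(out$manifest, fp("manifest.json"))
  invisible(outdir)
}
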