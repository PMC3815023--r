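two_group_expr <- function(n_genes, n1 = 10, n2 = 10, shift = NULL,
                           noise = 0.5, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * (n1 + n2), 8, noise), n_genes)
  if (!is.null(shift)) {
    vals[shift$genes, seq_len(n1)] <- vals[shift$genes, seq_len(n1)] + shift$lfc
  }
  rownames(vals) <- sprintf("g%04d", seq_len(n_genes))
  colnames(vals) <- sprintf("s%02d", seq_len(n1 + n2))
  expression_data(vals, tibble::tibble(
    sample_id = colnames(vals),
    group = rep(c("case", "control"), c(n1, n2))))
}

test_that("null p-values are uniform and planted genes rank on top", {
  expr <- two_group_expr(1000, seed = 3)
  de <- moderated_de(expr, "case", "control")
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 0.01)
  planted <- two_group_expr(500, shift = list(genes = 1:50, lfc = 2), seed = 4)
  de2 <- moderated_de(planted, "case", "control")
  expect_gt(mean(de2$score[1:50]), mean(de2$score[51:500]))
  expect_equal(mean(de2$effect[1:50]), 2, tolerance = 3 * 0.5 * sqrt(0.2) / sqrt(50))
})

test_that("moderated statistics agree with the limma cross-check", {
  library(limma)
  expr <- two_group_expr(400, shift = list(genes = 1:30, lfc = 1), seed = 5)
  de <- moderated_de(expr, "case", "control")
  design <- cbind(1, expr$samples$group == "case")
  fit <- eBayes(lmFit(expr$values, design))
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(de$df, unname(fit$df.total), tolerance = 1e-6)
})

test_that("the unmoderated path reduces to the ordinary pooled t-test", {
  expr <- two_group_expr(50, seed = 6)
  de <- moderated_de(expr, "case", "control", method = "pooled")
  for (i in c(1, 17, 50)) {
    tt <- t.test(expr$values[i, 1:10], expr$values[i, 11:20],
                 var.equal = TRUE)
    expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
  }
  dew <- moderated_de(expr, "case", "control", method = "welch")
  tw <- t.test(expr$values[1, 1:10], expr$values[1, 11:20])
  expect_equal(dew$p[1], tw$p.value, tolerance = 1e-10)
})

test_that("a constant gene with no difference gets p = 1", {
  vals <- matrix(rnorm(40, 8, 1), 4)
  vals[1, ] <- 5                   # flat, identical in both groups
  rownames(vals) <- paste0("g", 1:4)
  colnames(vals) <- paste0("s", 1:10)
  expr <- expression_data(vals, tibble::tibble(
    sample_id = colnames(vals), group = rep(c("case", "control"), each = 5)))
  de <- moderated_de(expr, "case", "control")
  expect_equal(de$p[1], 1)
  expect_equal(de$score[1], 0)
})

test_that("gene_score is -log10(p), strictly decreasing, and guards domain", {
  expect_equal(round(gene_score(0.05), 3), 1.301)
  expect_equal(gene_score(1), 0)
  expect_equal(gene_score(1e-6), 6)
  p <- sort(runif(20, 1e-8, 1))
  expect_true(all(diff(gene_score(p)) <= 0))
  expect_error(gene_score(0), "0, 1")
  expect_error(gene_score(-1), "0, 1")
  expect_error(gene_score(1.2), "0, 1")
})

test_that("absolute pathway scores average the three quartiles", {
  expect_equal(pathway_absolute_score(rep(2.5, 7))$absolute_score, 2.5)
  got <- pathway_absolute_score(c(1, 2, 3, 4, 5))
  expect_equal(got$absolute_score, 3)        # Q1=2, Q2=3, Q3=4
  expect_equal(got$absolute_level, 3L)
  expect_equal(got$absolute_score, oracle_quartile_mean(c(1, 2, 3, 4, 5)))
  set.seed(9)
  x <- rexp(11)
  expect_equal(pathway_absolute_score(x)$absolute_score,
               oracle_quartile_mean(x), tolerance = 1e-12)
  # order invariance and monotonicity in any member score
  expect_equal(pathway_absolute_score(rev(x)), pathway_absolute_score(x))
  y <- x
  y[3] <- y[3] + 1
  expect_gte(pathway_absolute_score(y)$absolute_score,
             pathway_absolute_score(x)$absolute_score)
})

test_that("level bins follow the published boundaries", {
  expect_equal(absolute_level(c(0, 1.3, 1.301, 1.99, 2, 2.5, 3, 4, 5.9, 6, 40)),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L))
  expect_equal(relative_level(c(0, 0.49, 0.5, 0.61, 0.7, 0.79, 0.8, 0.95, 1)),
               c(0L, 0L, 1L, 2L, 3L, 3L, 4L, 5L, 5L))
})

test_that("relative scores match exhaustive subset enumeration", {
  all_scores <- c(0.1, 0.4, 0.7, 1.1, 1.6, 2.2, 2.9, 3.7, 4.6, 5.6)
  members <- all_scores[8:10]
  obs <- quartile_mean(members)
  combos <- utils::combn(all_scores, 3)
  exact <- mean(apply(combos, 2, function(s) obs > quartile_mean(s)))
  got <- pathway_relative_score(members, all_scores, n_perm = 20000, seed = 2)
  expect_equal(got$relative_score, exact, tolerance = 0.02)
  # members = all measured genes: every permutation ties, strict > gives 0
  same <- pathway_relative_score(all_scores, all_scores, n_perm = 100, seed = 1)
  expect_equal(same$relative_score, 0)
  expect_equal(same$relative_level, 0L)
  expect_error(pathway_relative_score(1:11, all_scores), "larger")
  # deterministic given a seed
  expect_identical(pathway_relative_score(members, all_scores, 500, seed = 7),
                   pathway_relative_score(members, all_scores, 500, seed = 7))
})

test_that("score_pathways shares nulls correctly and flags empty sets", {
  de <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                       score = c(rep(5, 10), rexp(90, 2)))
  coll <- as_collection(list(hot = sprintf("g%03d", 1:10),
                             cold = sprintf("g%03d", 50:59),
                             absent = c("zz1", "zz2")))
  out <- score_pathways(coll, de, n_perm = 2000, seed = 3)
  expect_equal(out$n_members_measured, c(10L, 10L, 0L))
  expect_equal(out$absolute_score[1], 5)
  expect_gt(out$relative_score[1], 0.95)
  expect_true(is.na(out$absolute_score[3]))
  # single-set path agrees in distribution with the table path
  single <- pathway_relative_score(de$score[1:10], de$score,
                                   n_perm = 2000, seed = 11)
  expect_equal(out$relative_score[1], single$relative_score, tolerance = 0.05)
})

test_that("pair correlations summarise |r| by quartile mean per group", {
  set.seed(13)
  n <- 50
  vals <- rbind(a = rnorm(n), b = NA, c = rnorm(n), d = rnorm(n), e = 1)
  vals["b", ] <- vals["a", ] * 2 + 3          # perfectly correlated pair
  colnames(vals) <- paste0("s", seq_len(n))
  expr <- expression_data(vals, tibble::tibble(sample_id = colnames(vals),
                                               group = "all"))
  groups <- list(
    perfect = tibble::tibble(minus_gene = "a", plus_gene = "b"),
    noise = tibble::tibble(minus_gene = "c", plus_gene = "d"),
    flat = tibble::tibble(minus_gene = "a", plus_gene = "e"))
  out <- pair_correlation_summary(expr, groups)
  expect_equal(out$mean_abs_r[out$group == "perfect"], 1)
  expect_lt(out$mean_abs_r[out$group == "noise"], 0.3)
  expect_equal(out$n_skipped[out$group == "flat"], 1)  # constant profile
  expect_true(is.na(out$mean_abs_r[out$group == "flat"]))
})

test_that("independent noise pairs stay below 0.3 in most seeded runs", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    vals <- matrix(rnorm(40 * 50), 40)
    rownames(vals) <- sprintf("g%02d", 1:40)
    colnames(vals) <- sprintf("s%02d", 1:50)
    expr <- expression_data(vals, tibble::tibble(sample_id = colnames(vals),
                                                 group = "all"))
    prs <- tibble::tibble(minus_gene = sprintf("g%02d", 1:20),
                          plus_gene = sprintf("g%02d", 21:40))
    out <- pair_correlation_summary(expr, list(null = prs))
    if (out$mean_abs_r < 0.3) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.95)
})

test_that("interaction-rate cutoff groups are assembled as published", {
  sets <- list(s1 = sprintf("a%d", 1:10), s2 = sprintf("b%d", 1:10),
               s3 = sprintf("c%d", 1:10))
  prs <- tibble::tibble(
    minus_gene = c("a1", "a2", "a3", "b4", "x1"),
    plus_gene = c("b1", "b2", "c3", "c5", "x2"),
    chromosome = "chr1", tss_distance = 100)
  net <- build_set_network(as_collection(sets), prs, cutoff = 0.07)
  # rates: s1-s2 = 0.2, s1-s3 = 0.1, s2-s3 = 0.1
  grp <- pair_groups_from_network(net, prs, cutoffs = c(0.07, 0.1, 0.15))
  expect_setequal(names(grp), c("inter0.07", "inter0.1", "inter0.15", "other"))
  expect_equal(nrow(grp$inter0.07), 4)
  expect_equal(nrow(grp$inter0.15), 2)      # only the s1-s2 bridges
  expect_equal(grp$other$minus_gene, "x1")  # untouched pair
})

test_that("tissue variance separates planted housekeeping from specific", {
  sim <- sim_expression(sprintf("g%04d", 1:800),
                        groups = tibble::tibble(label = sprintf("t%02d", 1:10),
                                                n_samples = 3L),
                        housekeeping_fraction = 0.25,
                        tissue_specific_fraction = 0.25,
                        group_effect_sd = 1, seed = 21)
  gv <- gene_tissue_variance(sim$expr)
  v <- setNames(gv$tissue_variance, gv$gene_id)
  hk <- sim$gene_info$gene_id[sim$gene_info$class == "housekeeping"]
  ts <- sim$gene_info$gene_id[sim$gene_info$class == "tissue_specific"]
  expect_gt(mean(sample(v[ts], 500, replace = TRUE) >
                   sample(v[hk], 500, replace = TRUE)), 0.95)
  coll <- as_collection(list(hk_set = hk, ts_set = ts))
  bins <- tissue_variance_bins(sim$expr, coll)
  expect_lt(bins$variance[bins$set_name == "hk_set"],
            bins$variance[bins$set_name == "ts_set"])
  # bin boundaries
  expect_equal(dpgnet:::variance_bin(c(0.1, 0.45, 0.6, 0.71)),
               c("below_threshold", "low", "mid", "high"))
})

test_that("an all-flat matrix lands in the below-threshold bin", {
  vals <- matrix(8, 20, 9, dimnames = list(sprintf("g%02d", 1:20),
                                           sprintf("s%d", 1:9)))
  expr <- expression_data(vals, tibble::tibble(
    sample_id = colnames(vals), group = rep(paste0("t", 1:3), each = 3)))
  bins <- tissue_variance_bins(expr, as_collection(list(all = rownames(vals))))
  expect_equal(bins$variance, 0)
  expect_equal(bins$bin, "below_threshold")
})

test_that("housekeeping calling recovers planted genes with high accuracy", {
  sim <- sim_expression(sprintf("g%04d", 1:1000),
                        groups = tibble::tibble(label = sprintf("t%02d", 1:10),
                                                n_samples = 3L),
                        housekeeping_fraction = 1 / 3,
                        tissue_specific_fraction = 0.3,
                        group_effect_sd = 1, seed = 31)
  called <- call_housekeeping(sim$expr)
  truth <- sim$gene_info$gene_id[sim$gene_info$class == "housekeeping"]
  recall <- length(intersect(called, truth)) / length(truth)
  precision <- length(intersect(called, truth)) / length(called)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("housekeeping boundary behaviour is as documented", {
  vals <- rbind(hk = 10, silent = c(rep(10, 6), rep(0.1, 3)))
  vals <- vals + 0
  colnames(vals) <- paste0("s", 1:9)
  expr <- expression_data(vals, tibble::tibble(
    sample_id = colnames(vals), group = rep(paste0("t", 1:3), each = 3)))
  called <- call_housekeeping(expr, presence_threshold = 5)
  expect_true("hk" %in% called)       # present everywhere, zero variance
  expect_false("silent" %in% called)  # silent in one tissue
})

test_that("gene-list overlap statistics match direct enumeration", {
  prs <- make_pairs(10)
  # single list identical to the DPG genes: fraction 1, all pairs complete
  full <- list(all = dpg_genes(prs))
  st <- list_overlap_stats(full, prs)
  expect_equal(st$per_list$dpg_fraction, 1)
  expect_equal(st$n_complete_pairs, 10)
  # toy: {a,b,c} vs {b,c,d}
  st2 <- list_overlap_stats(list(l1 = c("a", "b", "c"),
                                 l2 = c("b", "c", "d")), prs)
  expect_equal(st2$intersection_size, 2)
  expect_equal(st2$union_size, 4)
  # 3 complete pairs + 2 half-pairs in the union: 6 genes organised in pairs
  lists <- list(u = c(prs$minus_gene[1:3], prs$plus_gene[1:3],
                      prs$minus_gene[4:5]))
  st3 <- list_overlap_stats(lists, prs)
  expect_equal(st3$n_complete_pairs, 3)
  expect_equal(st3$n_in_complete_pairs, 6)
  expect_equal(st3$n_union_dpg, 8)
})
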