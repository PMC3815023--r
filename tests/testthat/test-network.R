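# A small weighted network builder used across these tests: nodes named,
# edges supplied directly with weights, bypassing rate computation.
mock_network <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$a, edges$b)))
  structure(list(
    nodes = tibble::tibble(set_name = nodes, size = 10L, source = "set"),
    edges = tibble::tibble(set_a = edges$a, set_b = edges$b,
                           n_overlap_genes = 0L, overlap_rate = 0,
                           n_bridging = 1L, interaction_rate = edges$w,
                           bridging_pairs = replicate(nrow(edges),
                                                      make_pairs(0),
                                                      simplify = FALSE),
                           weight = edges$w),
    map_kind = "interaction", cutoff = 0, denominator = "min",
    coverage = list()), class = "dpg_set_network")
}

clique_edges <- function(nodes, w = 1) {
  cmb <- t(utils::combn(nodes, 2))
  data.frame(a = cmb[, 1], b = cmb[, 2], w = w)
}

test_that("overlap rate is the Simpson coefficient", {
  expect_equal(overlap_rate(letters[1:5], letters[1:10]), 1)      # A in B
  expect_equal(overlap_rate(letters[1:5], letters[10:20]), 0)     # disjoint
  expect_equal(overlap_rate(letters[1:10], letters[8:27]), 0.3)   # 3/min(10,20)
  expect_equal(overlap_rate(letters[1:10], letters[8:27]),
               overlap_rate(letters[8:27], letters[1:10]))
  expect_error(overlap_rate(character(), "a"), "non-empty")
})

test_that("interaction rate counts bridging pairs over the smaller set", {
  A <- sprintf("a%02d", 1:20)
  B <- sprintf("b%02d", 1:10)
  no_touch <- tibble::tibble(minus_gene = "x1", plus_gene = "x2",
                             chromosome = "chr1", tss_distance = 10)
  expect_equal(interaction_rate(A, B, no_touch)$n_bridging, 0)
  expect_equal(interaction_rate(A, B, no_touch)$rate, 0)
  prs <- tibble::tibble(minus_gene = c("a01", "b02"), plus_gene = c("b01", "a02"),
                        chromosome = "chr1", tss_distance = c(10, -10))
  got <- interaction_rate(A, B, prs)
  expect_equal(got$n_bridging, 2)
  expect_equal(got$rate, 0.2)
  # symmetric in its set arguments
  expect_equal(interaction_rate(B, A, prs)$rate, 0.2)
  # a pair inside the intersection does not bridge
  AB <- union(A, B)
  both_in <- tibble::tibble(minus_gene = "a01", plus_gene = "a02",
                            chromosome = "chr1", tss_distance = 10)
  expect_equal(interaction_rate(AB, A, both_in)$n_bridging, 0)
  # geometric-mean denominator option
  expect_equal(interaction_rate(A, B, prs, denominator = "geometric")$rate,
               2 / sqrt(200))
})

test_that("category filtering applies size > 5 and the greedy overlap rule", {
  coll <- as_collection(list(tiny = letters[1:5],           # size 5: dropped
                             six = letters[1:6]))
  out <- filter_categories(coll)
  expect_equal(out$set_name, "six")
  # identical duplicate sets: exactly one survives
  coll2 <- as_collection(list(dup1 = letters[1:10], dup2 = letters[1:10]))
  expect_equal(nrow(filter_categories(coll2)), 1)
  # greedy pass in descending size order, hand-executed oracle:
  # big(12) kept; over(10, 9/10 overlap with big) dropped; mid(8, disjoint)
  # kept; sub(6) subset of mid dropped; ok(6, overlap 4/6 < 0.8) kept
  coll3 <- as_collection(list(
    big = sprintf("g%02d", 1:12),
    over = sprintf("g%02d", c(1:9, 90)),
    mid = sprintf("h%02d", 1:8),
    sub = sprintf("h%02d", 1:6),
    ok = c(sprintf("h%02d", 1:4), "z1", "z2")))
  expect_setequal(filter_categories(coll3)$set_name, c("big", "mid", "ok"))
})

test_that("edge retention is strict and matches exhaustive rate computation", {
  sets <- list(s1 = sprintf("a%d", 1:8), s2 = sprintf("b%d", 1:8),
               s3 = c(sprintf("a%d", 1:4), sprintf("c%d", 1:4)),
               s4 = sprintf("d%d", 1:8), s5 = sprintf("e%d", 1:8))
  prs <- tibble::tibble(
    minus_gene = c("a1", "a2", "b1", "d1"),
    plus_gene = c("b2", "b3", "c1", "e1"),
    chromosome = "chr1", tss_distance = 100)
  net <- build_set_network(as_collection(sets), prs, "interaction", cutoff = 0)
  # brute force over all 10 set pairs
  for (i in 1:4) {
    for (j in (i + 1):5) {
      want <- interaction_rate(sets[[i]], sets[[j]], prs)
      row <- net$edges[net$edges$set_a == names(sets)[i] &
                         net$edges$set_b == names(sets)[j], ]
      if (want$rate > 0) {
        expect_equal(row$interaction_rate, want$rate)
        expect_equal(row$n_bridging, want$n_bridging)
      } else {
        expect_equal(nrow(row), 0)
      }
    }
  }
  # cutoff 1.0 leaves no edges (strict inequality, rates <= 1)
  expect_equal(nrow(build_set_network(as_collection(sets), prs,
                                      "interaction", cutoff = 1)$edges), 0)
  # default cutoffs
  expect_equal(build_set_network(as_collection(sets), prs)$cutoff, 0.07)
  expect_equal(build_set_network(as_collection(sets), prs,
                                 "overlap")$cutoff, 0.30)
})

test_that("coverage statistics count DPGs bridging retained edges", {
  sets <- list(s1 = c("m1", "x1"), s2 = c("p1", "x2"), s3 = c("m2", "x3"))
  prs <- tibble::tibble(minus_gene = c("m1", "m2"), plus_gene = c("p1", "p2"),
                        chromosome = "chr1", tss_distance = 100)
  net <- build_set_network(as_collection(sets), prs, cutoff = 0)
  # only pair (m1, p1) bridges s1-s2; m2 annotated but unbridged, p2 absent
  expect_equal(net$coverage$n_dpg_in_edges, 2)
  expect_equal(net$coverage$n_dpg_annotated, 3)
  expect_equal(net$coverage$relative_coverage_pct, 100 * 2 / 3)
  expect_equal(relative_coverage(0, 0), 0)
})

test_that("cohesiveness matches its formula and the brute-force oracle", {
  tri <- mock_network(clique_edges(c("a", "b", "c")))
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 1)
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 2), 1 / 3)
  # group with no internal edges
  path <- mock_network(data.frame(a = c("a", "b"), b = c("b", "c"), w = 1))
  expect_equal(cohesiveness(path, c("a", "c"), penalty = 2), 0)
  # random weighted graphs on <= 12 nodes: every subset agrees with oracle
  set.seed(33)
  for (rep in 1:3) {
    n <- sample(4:12, 1)
    nodes <- paste0("n", seq_len(n))
    full <- clique_edges(nodes)
    keep <- runif(nrow(full)) < 0.5
    edges <- full[keep, ]
    edges$w <- runif(nrow(edges))
    net <- mock_network(edges, nodes)
    for (k in 1:20) {
      members <- sample(nodes, sample(seq_len(n), 1))
      expect_equal(cohesiveness(net, members, penalty = 2),
                   oracle_cohesiveness(members, edges, 2),
                   tolerance = 1e-10)
    }
  }
  expect_error(cohesiveness(tri, character()), "non-empty")
})

test_that("greedy growth recovers cliques as cohesiveness optima", {
  # two unit-weight cliques joined by one feeble edge
  k4 <- paste0("a", 1:4)
  k5 <- paste0("b", 1:5)
  edges <- rbind(clique_edges(k4), clique_edges(k5),
                 data.frame(a = "a1", b = "b1", w = 0.01))
  net <- mock_network(edges)
  mods <- cluster_modules(net, penalty = 2)
  expect_equal(nrow(mods), 2)
  expect_setequal(mods$members[[1]], k5)
  expect_setequal(mods$members[[2]], k4)
  # exhaustive subset search on this 9-node graph confirms each module is
  # the best group among all subsets containing its seed-side nodes
  nodes <- c(k4, k5)
  best_f <- -Inf
  best_set <- NULL
  for (mask in 1:(2^9 - 1)) {
    members <- nodes[as.logical(bitwAnd(mask, 2^(0:8)))]
    f <- oracle_cohesiveness(members, edges, 2)
    if (f > best_f) {
      best_f <- f
      best_set <- members
    }
  }
  expect_setequal(best_set, k5)
  expect_equal(mods$cohesiveness[[1]], best_f, tolerance = 1e-10)
  # the K5 module p-value: 10 internal unit weights vs one 0.01 boundary
  expect_lt(mods$p_value[[1]], 0.2)
})

test_that("a lone triangle is one module and empty networks yield none", {
  tri <- mock_network(clique_edges(c("a", "b", "c")))
  mods <- cluster_modules(tri, penalty = 2)
  expect_equal(nrow(mods), 1)
  expect_setequal(mods$members[[1]], c("a", "b", "c"))
  expect_true(is.na(mods$p_value[[1]]))   # no boundary edges to compare
  empty <- mock_network(clique_edges(c("a", "b", "c"))[0, ])
  expect_equal(nrow(cluster_modules(empty)), 0)
})

test_that("the merge step uses the Simpson coefficient threshold", {
  # Simpson 2/3 < 0.8: not merged
  expect_equal(length(dpgnet:::merge_groups(list(c("a", "b", "c"),
                                                 c("b", "c", "d")), 0.8)), 2)
  # Simpson 1 (subset): merged transitively
  merged <- dpgnet:::merge_groups(list(c("a", "b", "c"), c("b", "c"),
                                       c("b", "c", "e")), 0.8)
  expect_equal(length(merged), 1)
  expect_setequal(merged[[1]], c("a", "b", "c", "e"))
})

test_that("a planted three-block collection yields exactly three modules", {
  blocks <- lapply(1:3, function(b) {
    lapply(1:5, function(s) {
      sprintf("blk%d_g%02d", b, (s - 1) * 10 + 1:10)  # disjoint sets
    })
  })
  sets <- unlist(blocks, recursive = FALSE)
  names(sets) <- sprintf("set_b%d_%d", rep(1:3, each = 5), rep(1:5, 3))
  # DPG pairs bridge consecutive sets within each block only
  prs <- dplyr::bind_rows(lapply(1:3, function(b) {
    dplyr::bind_rows(lapply(1:4, function(s) {
      tibble::tibble(
        minus_gene = sprintf("blk%d_g%02d", b, (s - 1) * 10 + 1:3),
        plus_gene = sprintf("blk%d_g%02d", b, s * 10 + 1:3),
        chromosome = "chr1", tss_distance = 100)
    }))
  }))
  net <- build_set_network(as_collection(sets), prs, "interaction",
                           cutoff = 0.07)
  mods <- cluster_modules(net)
  expect_equal(nrow(mods), 3)
  for (b in 1:3) {
    hit <- vapply(mods$members,
                  function(m) any(grepl(sprintf("set_b%d_", b), m)),
                  logical(1))
    expect_equal(sum(hit), 1)                     # block maps to one module
    expect_setequal(mods$members[[which(hit)]],
                    sprintf("set_b%d_%d", b, 1:5)) # and covers it exactly
  }
  # determinism: same inputs, same modules
  expect_identical(tidy(mods), tidy(cluster_modules(net)))
})

test_that("set fractions report the published percentage convention", {
  coll <- as_collection(list(nhej = sprintf("g%02d", 1:13)))
  out <- dpg_set_fractions(coll, sprintf("g%02d", 1:6))
  expect_equal(out$n_dpg, 6)
  expect_equal(out$dpg_pct, 100 * 6 / 13)
})
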