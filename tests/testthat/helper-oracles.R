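# Independent brute-force oracles and small fixtures, kept deliberately
# naive and separate from the package's own code paths.

# Exhaustive all-pairs DPG scan with the same tie-breaking rule:
# O(n^2) loops, no sorting tricks.
oracle_find_dpgs <- function(genes, window = 1000, require_adjacent = TRUE) {
  genes <- dpgnet::gene_table(genes)
  cands <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      gi <- genes[i, ]
      gj <- genes[j, ]
      if (gi$strand != "-" || gj$strand != "+") next
      if (gi$chromosome != gj$chromosome) next
      d <- gj$tss - gi$tss
      if (d == 0 || abs(d) >= window) next
      if (require_adjacent) {
        lo <- min(gi$tss, gj$tss)
        hi <- max(gi$tss, gj$tss)
        others <- genes$tss[genes$chromosome == gi$chromosome &
                              !(genes$gene_id %in% c(gi$gene_id, gj$gene_id))]
        if (any(others > lo & others < hi)) next
      }
      cands[[length(cands) + 1L]] <-
        data.frame(minus_gene = gi$gene_id, plus_gene = gj$gene_id,
                   tss_distance = d)
    }
  }
  if (length(cands) == 0L) {
    return(data.frame(minus_gene = character(), plus_gene = character(),
                      tss_distance = numeric()))
  }
  cands <- do.call(rbind, cands)
  cands <- cands[order(abs(cands$tss_distance), cands$minus_gene,
                       cands$plus_gene), ]
  used <- character()
  keep <- logical(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    if (!(cands$minus_gene[k] %in% used) && !(cands$plus_gene[k] %in% used)) {
      keep[k] <- TRUE
      used <- c(used, cands$minus_gene[k], cands$plus_gene[k])
    }
  }
  cands[keep, ]
}

# Ancestor set by naive recursion over an explicit parent list.
oracle_ancestors <- function(term, parents) {
  out <- term
  for (p in parents[[term]]) {
    out <- union(out, oracle_ancestors(p, parents))
  }
  out
}

# Schlicker relevance similarity by exhaustive common-ancestor enumeration
# on plain named vectors (p, ic) and a parent list.
oracle_term_sim <- function(t1, t2, p, ic, parents) {
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(0)
  common <- intersect(oracle_ancestors(t1, parents), oracle_ancestors(t2, parents))
  common <- intersect(common, names(ic))
  if (length(common) == 0) return(0)
  max(sapply(common, function(a) 2 * ic[[a]] / denom * (1 - p[[a]])))
}

oracle_rcmax_avg <- function(m) {
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (nrow(m) + ncol(m))
}

# Two-sample KS statistic as a sup over the pooled grid of ECDF differences.
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  f1 <- sapply(grid, function(g) mean(x <= g))
  f2 <- sapply(grid, function(g) mean(y <= g))
  max(abs(f1 - f2))
}

# Hypergeometric upper tail by direct summation of choose() terms.
oracle_hyper_upper <- function(k, K, N, n) {
  sum(sapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }))
}

# Cohesiveness from the definition, on an edge data frame (a, b, w).
oracle_cohesiveness <- function(members, edges, penalty) {
  w_in <- sum(edges$w[edges$a %in% members & edges$b %in% members])
  w_bound <- sum(edges$w[xor(edges$a %in% members, edges$b %in% members)])
  denom <- w_in + w_bound + penalty * length(members)
  if (denom == 0) 0 else w_in / denom
}

# Quartile mean from first principles (type-7 interpolation, spelled out).
oracle_quartile_mean <- function(x) {
  s <- sort(x)
  n <- length(s)
  q <- sapply(c(0.25, 0.5, 0.75), function(pr) {
    h <- (n - 1) * pr + 1
    lo <- floor(h)
    if (lo == n) s[n] else s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  })
  mean(q)
}

# A small hand-made two-namespace ontology used across similarity tests:
#   CC: root -> a -> c, root -> b -> c (c has two parents), b -> d
#   BP: root2 -> x
toy_ontology <- function() {
  terms <- tibble::tibble(
    term_id = c("CC:root", "CC:a", "CC:b", "CC:c", "CC:d", "BP:root", "BP:x"),
    name = term_id,
    namespace = c(rep("CC", 5), rep("BP", 2)))
  parents <- list(
    "CC:root" = character(), "CC:a" = "CC:root", "CC:b" = "CC:root",
    "CC:c" = c("CC:a", "CC:b"), "CC:d" = "CC:b",
    "BP:root" = character(), "BP:x" = "BP:root")
  dpgnet::ontology(terms, parents)
}

# Annotations over 10 genes giving easy hand-countable IC values:
# genes t1..t5 hit the CC:a side, t6..t10 the CC:b side.
toy_annotations <- function() {
  tibble::tibble(
    gene_id = c(paste0("t", 1:5), paste0("t", 6:9), "t10",
                paste0("t", 1:10)),
    term_id = c(rep("CC:a", 3), rep("CC:c", 2), rep("CC:b", 2),
                rep("CC:d", 2), "CC:b", rep("BP:x", 10)),
    evidence = "IDA")
}

# Deterministic planted-pair tibble over ad-hoc gene ids.
make_pairs <- function(n) {
  tibble::tibble(minus_gene = sprintf("m%04d", seq_len(n)),
                 plus_gene = sprintf("p%04d", seq_len(n)),
                 chromosome = "chr1",
                 tss_distance = rep(c(400, -300), length.out = n))
}
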