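#' Simulate a genome with planted head-to-head gene pairs
#'
#' Generates a gene coordinate table in which exactly `n_planted_pairs`
#' adjacent opposite-strand pairs have a signed TSS distance inside the open
#' `(-window, window)` interval, and every other gene sits at least
#' `min_intergene_gap` bp from its neighbours so no unplanted head-to-head
#' pair exists. The defaults emulate the composition of the published human
#' DPG table: 864 pairs among 17,280 genes (pairs are ~10% of genes), with
#' 682/864 of the pairs at positive TSS distance.
#'
#' @param n_genes Total number of genes.
#' @param n_planted_pairs Number of planted divergent pairs
#'   (`2 * n_planted_pairs <= n_genes`).
#' @param chromosome_lengths Lengths (bp) of the chromosomes.
#' @param tss_distance_range Interval the planted signed TSS distances are
#'   drawn from; must sit inside (-1000, 1000) and exclude 0.
#' @param prop_positive Proportion of planted distances that are positive;
#'   the positive count is exact (`round(prop_positive * n)` per chromosome
#'   batch), emulating the published 682-of-864 split.
#' @param min_intergene_gap Minimum gap (bp) between unrelated neighbouring
#'   genes; must exceed 1000 so unplanted genes cannot pair.
#' @param gene_length_range Gene body lengths are drawn uniformly from this
#'   interval.
#' @param seed Optional seed; identical seeds give identical output.
#' @return List with `genes` (a [gene_table()]) and `truth` (tibble of the
#'   planted pairs: `minus_gene`, `plus_gene`, `chromosome`, `tss_distance`).
#' @export
sim_genome <- function(n_genes = 17280,
                       n_planted_pairs = 864,
                       chromosome_lengths = rep(8e6, 24),
                       tss_distance_range = c(-950, 950),
                       prop_positive = 682 / 864,
                       min_intergene_gap = 5000,
                       gene_length_range = c(1000, 3000),
                       seed = NULL) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  check_scalar_number(n_planted_pairs, "n_planted_pairs", lower = 0)
  if (2 * n_planted_pairs > n_genes) {
    abort("need 2 * n_planted_pairs <= n_genes.")
  }
  if (tss_distance_range[1] <= -1000 || tss_distance_range[2] >= 1000) {
    abort("`tss_distance_range` must lie inside (-1000, 1000).")
  }
  if (min_intergene_gap <= 1000) {
    abort("`min_intergene_gap` must exceed 1000 bp.")
  }
  if (any(chromosome_lengths <= 0)) {
    abort("chromosome lengths must be positive.")
  }
  with_seed(seed, {
    n_chrom <- length(chromosome_lengths)
    chrom_names <- sprintf("chr%d", seq_len(n_chrom))
    n_single <- n_genes - 2L * n_planted_pairs
    # one "unit" = a planted pair or a single gene
    unit_is_pair <- sample(c(rep(TRUE, n_planted_pairs), rep(FALSE, n_single)))
    n_units <- length(unit_is_pair)
    # apportion units to chromosomes proportionally to length
    share <- chromosome_lengths / sum(chromosome_lengths)
    alloc <- floor(share * n_units)
    rem <- n_units - sum(alloc)
    if (rem > 0) {
      bump <- order(share * n_units - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[bump] <- alloc[bump] + 1L
    }
    unit_chrom <- rep(seq_len(n_chrom), alloc)

    # planted signed distances, drawn globally so the positive count is exact
    d_all <- integer(0)
    if (n_planted_pairs > 0) {
      pos_lo <- max(1, tss_distance_range[1])
      pos_hi <- tss_distance_range[2]
      neg_lo <- tss_distance_range[1]
      neg_hi <- min(-1, tss_distance_range[2])
      p_pos <- prop_positive
      if (pos_hi < pos_lo) p_pos <- 0
      if (neg_hi < neg_lo) p_pos <- 1
      n_pos <- round(p_pos * n_planted_pairs)
      pos <- sample(c(rep(TRUE, n_pos), rep(FALSE, n_planted_pairs - n_pos)))
      d_pos <- if (pos_hi >= pos_lo) {
        sample(pos_lo:pos_hi, n_planted_pairs, replace = TRUE)
      } else {
        integer(n_planted_pairs)
      }
      d_neg <- if (neg_hi >= neg_lo) {
        sample(neg_lo:neg_hi, n_planted_pairs, replace = TRUE)
      } else {
        integer(n_planted_pairs)
      }
      d_all <- ifelse(pos, d_pos, d_neg)
    }
    pairs_taken <- 0L

    lmin <- gene_length_range[1]
    lmax <- gene_length_range[2]
    gene_rows <- vector("list", n_chrom)
    truth_rows <- vector("list", n_chrom)
    gid <- 0L
    next_id <- function() sprintf("g%06d", gid)

    for (ch in seq_len(n_chrom)) {
      is_pair <- unit_is_pair[unit_chrom == ch]
      nu <- length(is_pair)
      if (nu == 0L) {
        next
      }
      len1 <- sample(lmin:lmax, nu, replace = TRUE)
      len2 <- sample(lmin:lmax, nu, replace = TRUE)
      d <- integer(nu)
      if (any(is_pair)) {
        np <- sum(is_pair)
        d[is_pair] <- d_all[pairs_taken + seq_len(np)]
        pairs_taken <- pairs_taken + np
      }
      span <- ifelse(is_pair, len1 + pmax(0L, d) + len2, len1)
      needed <- sum(span) + (nu + 1) * min_intergene_gap
      if (needed > chromosome_lengths[ch]) {
        abort(sprintf(
          "infeasible packing: %d genes need %d bp on %s (%d bp available).",
          sum(is_pair) * 2L + sum(!is_pair), needed, chrom_names[ch],
          as.integer(chromosome_lengths[ch])))
      }
      slack <- chromosome_lengths[ch] - needed
      cuts <- sort(runif(nu, 0, slack))
      extra <- floor(diff(c(0, cuts)))
      pos0 <- cumsum(min_intergene_gap + extra + c(0, span[-nu]))
      rows <- vector("list", nu)
      truths <- vector("list", nu)
      for (u in seq_len(nu)) {
        p0 <- pos0[u]
        if (is_pair[u]) {
          gid <- gid + 1L
          id_m <- next_id()
          gid <- gid + 1L
          id_p <- next_id()
          # minus gene TSS at its right end; plus gene TSS = minus TSS + d
          tss_m <- p0 + len1[u] - 1L
          rows[[u]] <- tibble(
            gene_id = c(id_m, id_p), chromosome = chrom_names[ch],
            strand = c("-", "+"),
            start = c(p0, tss_m + d[u]),
            end = c(p0 + len1[u], tss_m + d[u] + len2[u]))
          truths[[u]] <- tibble(minus_gene = id_m, plus_gene = id_p,
                                chromosome = chrom_names[ch],
                                tss_distance = as.numeric(d[u]))
        } else {
          gid <- gid + 1L
          rows[[u]] <- tibble(gene_id = next_id(), chromosome = chrom_names[ch],
                              strand = sample(c("+", "-"), 1L),
                              start = p0, end = p0 + len1[u])
        }
      }
      gene_rows[[ch]] <- bind_rows(rows)
      truth_rows[[ch]] <- bind_rows(truths)
    }
    genes <- gene_table(bind_rows(gene_rows))
    truth <- bind_rows(truth_rows)
    if (nrow(truth) == 0L) {
      truth <- empty_pairs()[, 1:4]
    }
    list(genes = genes, truth = truth)
  })
}
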