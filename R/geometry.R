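#' Build a validated gene coordinate table
#'
#' Coordinates are 0-based, half-open (BED convention). The transcription
#' start site (TSS) is `start` for plus-strand genes and `end - 1` for
#' minus-strand genes; a `tss` column is derived if absent.
#'
#' @param genes Data frame with columns `gene_id`, `chromosome`, `strand`
#'   (`"+"` or `"-"`), `start`, `end`.
#' @return A tibble with the input columns plus `tss`.
#' @examples
#' gene_table(data.frame(gene_id = "a", chromosome = "chr1",
#'                       strand = "+", start = 100, end = 500))
#' @export
gene_table <- function(genes) {
  genes <- as_tibble(genes)
  needed <- c("gene_id", "chromosome", "strand", "start", "end")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0L) {
    abort(paste0("gene table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("`strand` must be \"+\" or \"-\" for every gene.")
  }
  if (any(genes$start >= genes$end)) {
    abort("every gene must satisfy start < end (0-based, half-open).")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene ids in gene table.")
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes
}

#' Signed TSS distance of a head-to-head gene pair
#'
#' Returns `tss(plus) - tss(minus)`: positive when the two TSSs diverge
#' without overlap, negative when the plus-strand TSS lies to the left of
#' the minus-strand TSS (overlapping 5' regions).
#'
#' @param minus_gene,plus_gene One-row data frames (or lists) with
#'   `chromosome`, `strand` and `tss` fields, e.g. rows of a [gene_table()].
#' @return Signed distance in base pairs.
#' @export
tss_distance <- function(minus_gene, plus_gene) {
  minus_gene <- as.list(minus_gene)
  plus_gene <- as.list(plus_gene)
  if (!identical(minus_gene$strand, "-") || !identical(plus_gene$strand, "+")) {
    abort("`minus_gene` must be on the - strand and `plus_gene` on the + strand.")
  }
  if (!identical(minus_gene$chromosome, plus_gene$chromosome)) {
    abort("both genes must lie on the same chromosome.")
  }
  as.numeric(plus_gene$tss) - as.numeric(minus_gene$tss)
}

#' Identify divergently paired genes (DPGs)
#'
#' Finds opposite-strand gene pairs whose signed TSS distance lies strictly in
#' `(-window, 0) | (0, window)`. Each gene joins at most one pair: candidate
#' pairs are accepted greedily by smallest absolute TSS distance, ties broken
#' by lexicographic gene ids. By default pairs must also be adjacent in TSS
#' order (no third gene's TSS strictly between the two TSSs).
#'
#' @param genes A [gene_table()] (or coercible data frame).
#' @param window Open half-width of the TSS-distance interval, in bp.
#' @param require_adjacent Require TSS adjacency of the two members.
#' @return Tibble with columns `minus_gene`, `plus_gene`, `chromosome`,
#'   `tss_distance`, `distance_class` (`"positive"`/`"negative"`).
#' @export
find_dpgs <- function(genes, window = 1000, require_adjacent = TRUE) {
  genes <- gene_table(genes)
  check_scalar_number(window, "window", lower = 1)
  cands <- dpg_candidates(genes, window, require_adjacent)
  if (nrow(cands) == 0L) {
    return(empty_pairs())
  }
  # greedy one-to-one matching: smallest |distance| first, then lexicographic ids
  cands <- cands[order(abs(cands$tss_distance), cands$minus_gene, cands$plus_gene), ]
  used <- new.env(parent = emptyenv())
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    m <- cands$minus_gene[i]
    p <- cands$plus_gene[i]
    if (is.null(used[[m]]) && is.null(used[[p]])) {
      keep[i] <- TRUE
      used[[m]] <- TRUE
      used[[p]] <- TRUE
    }
  }
  out <- cands[keep, ]
  out <- out[order(out$chromosome, pmin(out$minus_gene, out$plus_gene)), ]
  out$distance_class <- ifelse(out$tss_distance > 0, "positive", "negative")
  as_tibble(out[, c("minus_gene", "plus_gene", "chromosome",
                    "tss_distance", "distance_class")])
}

empty_pairs <- function() {
  tibble(minus_gene = character(), plus_gene = character(),
         chromosome = character(), tss_distance = numeric(),
         distance_class = character())
}

# All candidate opposite-strand pairs within the open window, before matching.
dpg_candidates <- function(genes, window, require_adjacent) {
  per_chrom <- split(genes, genes$chromosome)
  rows <- lapply(per_chrom, function(g) {
    n <- nrow(g)
    if (n < 2L) {
      return(NULL)
    }
    g <- g[order(g$tss, g$gene_id), ]
    ts <- g$tss
    # last index j with ts[j] < ts[i] + window  (strict inequality)
    hi <- findInterval(ts + window - 0.5, ts)
    n_each <- pmax(hi - seq_len(n), 0L)
    if (sum(n_each) == 0L) {
      return(NULL)
    }
    i <- rep.int(seq_len(n), n_each)
    j <- sequence(n_each, from = seq_len(n) + 1L)
    ok <- g$strand[i] != g$strand[j] & ts[j] != ts[i]
    i <- i[ok]
    j <- j[ok]
    if (length(i) == 0L) {
      return(NULL)
    }
    if (require_adjacent) {
      # count TSSs strictly inside the open interval (ts[i], ts[j])
      n_between <- findInterval(ts[j] - 0.5, ts) - findInterval(ts[i] + 0.5, ts)
      adj <- n_between == 0L
      i <- i[adj]
      j <- j[adj]
      if (length(i) == 0L) {
        return(NULL)
      }
    }
    minus_first <- g$strand[i] == "-"
    mi <- ifelse(minus_first, i, j)
    pi <- ifelse(minus_first, j, i)
    tibble(minus_gene = g$gene_id[mi],
           plus_gene = g$gene_id[pi],
           chromosome = g$chromosome[1],
           tss_distance = ts[pi] - ts[mi])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) empty_pairs()[, 1:4] else out
}

#' Summarise TSS-distance classes of a pair table
#'
#' @param pairs Pair tibble from [find_dpgs()].
#' @return Tibble with `n_pairs`, `n_genes`, `n_positive`, `n_negative`.
#' @export
count_distance_classes <- function(pairs) {
  tibble(n_pairs = nrow(pairs),
         n_genes = length(unique(c(pairs$minus_gene, pairs$plus_gene))),
         n_positive = sum(pairs$tss_distance > 0),
         n_negative = sum(pairs$tss_distance < 0))
}

#' Gene ids belonging to DPG pairs
#'
#' @param pairs Pair tibble from [find_dpgs()].
#' @return Character vector of member gene ids.
#' @export
dpg_genes <- function(pairs) {
  unique(c(pairs$minus_gene, pairs$plus_gene))
}

#' Chromosome enrichment of DPG genes
#'
#' Per chromosome, the hypergeometric tail probability of observing at least
#' (over-enrichment) or at most (under-enrichment) the observed number of DPG
#' genes when drawing that chromosome's genes from the genome-wide pool. The
#' smaller tail is reported with its direction, plus Benjamini-Hochberg
#' adjusted values across chromosomes.
#'
#' @param genes A [gene_table()].
#' @param dpg_gene_ids Character vector of DPG member gene ids (subset of the
#'   table's genes).
#' @param chromosomes Optional chromosome universe; chromosomes without genes
#'   get `p_value = 1` and direction `"none"`.
#' @return Tibble with one row per chromosome: `chromosome`, `n_genes`,
#'   `n_dpg_genes`, `p_value`, `p_adjusted`, `enrichment_direction`.
#' @export
chromosome_enrichment <- function(genes, dpg_gene_ids, chromosomes = NULL) {
  genes <- gene_table(genes)
  if (!all(dpg_gene_ids %in% genes$gene_id)) {
    abort("`dpg_gene_ids` must all be present in the gene table.")
  }
  chromosomes <- chromosomes %||% sort(unique(genes$chromosome))
  is_dpg <- genes$gene_id %in% dpg_gene_ids
  total <- nrow(genes)
  total_dpg <- sum(is_dpg)
  rows <- lapply(chromosomes, function(ch) {
    on_ch <- genes$chromosome == ch
    k <- sum(on_ch)
    q <- sum(on_ch & is_dpg)
    if (k == 0L) {
      return(tibble(chromosome = ch, n_genes = 0L, n_dpg_genes = 0L,
                    p_value = 1, enrichment_direction = "none"))
    }
    p_over <- phyper(q - 1, total_dpg, total - total_dpg, k, lower.tail = FALSE)
    p_under <- phyper(q, total_dpg, total - total_dpg, k)
    if (p_over < p_under) {
      tibble(chromosome = ch, n_genes = k, n_dpg_genes = q,
             p_value = p_over, enrichment_direction = "over")
    } else if (p_under < p_over) {
      tibble(chromosome = ch, n_genes = k, n_dpg_genes = q,
             p_value = p_under, enrichment_direction = "under")
    } else {
      tibble(chromosome = ch, n_genes = k, n_dpg_genes = q,
             p_value = p_over, enrichment_direction = "none")
    }
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(pmin(out$p_value, 1), method = "BH")
  out[, c("chromosome", "n_genes", "n_dpg_genes", "p_value", "p_adjusted",
          "enrichment_direction")]
}
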