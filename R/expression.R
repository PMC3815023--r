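#' Expression data container
#'
#' Log2-scale expression values (genes by samples) plus a sample sheet with
#' group labels and optional tissue labels. All downstream scoring assumes
#' log-scale input, matching microarray practice.
#'
#' @param values Numeric matrix, rows named by gene id, columns by sample id.
#' @param samples Tibble with columns `sample_id`, `group`, and optionally
#'   `tissue`.
#' @return Object of class `dpg_expression`.
#' @export
expression_data <- function(values, samples) {
  samples <- as_tibble(samples)
  stopifnot(is.matrix(values), all(c("sample_id", "group") %in% names(samples)))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort("`values` must have unique gene-id rownames.")
  }
  if (!identical(colnames(values), samples$sample_id)) {
    abort("column names of `values` must equal `samples$sample_id` in order.")
  }
  structure(list(values = values, samples = samples), class = "dpg_expression")
}

#' @export
print.dpg_expression <- function(x, ...) {
  cat(sprintf("<dpg_expression> %d genes x %d samples, %d group(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$group))))
  invisible(x)
}

#' Long-format view of expression data
#'
#' @param x A [expression_data()] object.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `sample_id`, `group`, (`tissue`,) `value`.
#' @export
tidy.dpg_expression <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value")
  left_join(long, x$samples, by = "sample_id")
}

group_columns <- function(expr, group) {
  idx <- which(expr$samples$group %in% group)
  if (length(idx) == 0L) {
    abort(sprintf("no samples in group(s) %s.", paste(group, collapse = ", ")))
  }
  idx
}

#' Moderated two-sample differential expression
#'
#' Per gene, a two-sample t-test on log2 values with empirical-Bayes variance
#' moderation: the pooled sample variances are shrunk toward a common prior by
#' `s2_tilde = (d0 * s0^2 + dg * s2_g) / (d0 + dg)`, where the prior degrees
#' of freedom `d0` and prior variance `s0^2` are fitted by moment-matching the
#' scaled-F distribution of the sample variances (digamma/trigamma inversion
#' on log variances; genes with zero residual df are excluded from the fit).
#' The moderated t has `d0 + dg` degrees of freedom. A plain Welch t-test and
#' an unmoderated pooled t are available via `method`.
#'
#' @param expr A [expression_data()] object.
#' @param case,control Group labels (each with >= 2 samples).
#' @param method `"moderated"` (default), `"pooled"` or `"welch"`.
#' @return Tibble with `gene_id`, `effect` (case minus control log2
#'   difference), `t`, `df`, `p`, `score` (`-log10(p)`).
#' @export
moderated_de <- function(expr, case, control,
                         method = c("moderated", "pooled", "welch")) {
  method <- match.arg(method)
  i1 <- group_columns(expr, case)
  i2 <- group_columns(expr, control)
  if (length(i1) < 2L || length(i2) < 2L) {
    abort("both groups need at least 2 samples.")
  }
  x1 <- expr$values[, i1, drop = FALSE]
  x2 <- expr$values[, i2, drop = FALSE]
  n1 <- length(i1)
  n2 <- length(i2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  effect <- m1 - m2
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    tt <- effect / sqrt(se2)
  } else {
    dg <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
    if (method == "moderated") {
      prior <- fit_f_dist(s2, dg)
      if (is.finite(prior$d0)) {
        s2_tilde <- (prior$d0 * prior$s0 + dg * s2) / (prior$d0 + dg)
      } else {
        s2_tilde <- rep(prior$s0, length(s2))  # infinite prior df: common variance
      }
      # total df capped at the pooled residual df across genes: the prior
      # cannot carry more information than the data it was fitted to
      df <- rep(min(prior$d0 + dg, length(s2) * dg), length(s2))
    } else {
      s2_tilde <- s2
      df <- rep(dg, length(s2))
    }
    tt <- effect / sqrt(s2_tilde * (1 / n1 + 1 / n2))
  }
  tt[is.nan(tt)] <- 0          # zero variance and zero difference
  p <- 2 * pt(-abs(tt), df)
  p <- pmin(pmax(p, 1e-300), 1)
  tibble(gene_id = rownames(expr$values), effect = unname(effect),
         t = unname(tt), df = unname(df), p = unname(p),
         score = -log10(unname(p)))
}

# Moment-matching fit of a scaled F prior to sample variances (on log scale).
# Zero variances are offset to a tiny fraction of the median before taking
# logs; genes with non-finite variance are excluded.
fit_f_dist <- function(s2, df) {
  x <- pmax(s2[is.finite(s2)], 0)
  n <- length(x)
  if (n < 2L) {
    return(list(d0 = 0, s0 = if (n == 1L) x else NA_real_))
  }
  m <- median(x)
  if (m == 0) {
    m <- 1
  }
  x <- pmax(x, 1e-5 * m)
  e <- log(x) - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- sum((e - e_mean)^2) / (n - 1L) - trigamma(df / 2)
  if (is.na(e_var) || e_var <= 0) {
    # variances more concordant than chi-square sampling alone: infinite
    # prior df collapses every gene to the common variance
    return(list(d0 = Inf, s0 = mean(x)))
  }
  d0 <- 2 * trigamma_inverse(e_var)
  s0 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0 = s0)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(y) {
  if (y <= 0) {
    return(Inf)
  }
  if (y > 1e7) {
    return(1 / sqrt(y))
  }
  if (y < 1e-6) {
    return(1 / y)
  }
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Convert a differential-expression p-value to a gene score
#'
#' `score = -log10(p)`; e.g. p = 0.05 gives 1.301, the no-perturbation bound.
#'
#' @param p Probabilities in `(0, 1]`.
#' @return Non-negative scores.
#' @export
gene_score <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  -log10(p)
}

#' Perturbation level of an absolute pathway score
#'
#' Bins (left-closed, right-open): `[0, 1.301)` level 0 (no perturbation),
#' `[1.301, 2)` 1, `[2, 3)` 2, `[3, 4)` 3, `[4, 6)` 4, `[6, Inf)` 5 -
#' matching p-value ranges 0.05-0.01, 0.01-1e-3, 1e-3-1e-4, 1e-4-1e-6, <1e-6.
#'
#' @param score Non-negative absolute scores.
#' @return Integer levels 0-5.
#' @export
absolute_level <- function(score) {
  # 1.301 is the printed three-decimal boundary (-log10(0.05) = 1.30103...);
  # using it literally keeps the published bin edges exact
  breaks <- c(0, 1.301, 2, 3, 4, 6, Inf)
  as.integer(cut(score, breaks = breaks, right = FALSE,
                 include.lowest = TRUE)) - 1L
}

#' Perturbation level of a relative pathway score
#'
#' Bins: `[0, 0.5)` level 0, then `[0.5, 0.6)`, `[0.6, 0.7)`, `[0.7, 0.8)`,
#' `[0.8, 0.9)` and `[0.9, 1]` for levels 1-5.
#'
#' @param score Relative scores in `[0, 1]`.
#' @return Integer levels 0-5.
#' @export
relative_level <- function(score) {
  breaks <- c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1 + 1e-9)
  as.integer(cut(score, breaks = breaks, right = FALSE,
                 include.lowest = TRUE)) - 1L
}

#' Absolute pathway score of a member-score vector
#'
#' The mean of the three quartiles (Q1, Q2, Q3) of the member genes'
#' `-log10(p)` scores, with its perturbation level.
#'
#' @param scores Member gene scores (at least one).
#' @param quartile_type Quantile convention, see [quartile_mean()].
#' @return Tibble with `absolute_score`, `absolute_level`, `n_members`.
#' @export
pathway_absolute_score <- function(scores, quartile_type = 7) {
  s <- quartile_mean(scores, quartile_type)
  tibble(absolute_score = s, absolute_level = absolute_level(s),
         n_members = sum(is.finite(scores)))
}

#' Relative pathway score by permutation
#'
#' The observed statistic is the absolute pathway score of the member genes.
#' Its null is the same statistic on `n_perm` random gene sets of the same
#' size, drawn without replacement from all measured genes; the relative
#' score is the fraction of permutations the observed statistic strictly
#' exceeds, with its perturbation level. The published analyses used ten
#' thousand permutations.
#'
#' @param member_scores Scores of the member genes (e.g. the DPG genes in a
#'   pathway).
#' @param all_scores Scores of all measured genes (the permutation pool).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Optional seed.
#' @param quartile_type Quantile convention.
#' @return Tibble with `relative_score`, `relative_level`, `n_members`,
#'   `n_perm`.
#' @export
pathway_relative_score <- function(member_scores, all_scores, n_perm = 10000,
                                   seed = NULL, quartile_type = 7) {
  m <- length(member_scores)
  if (m == 0L) {
    abort("`member_scores` must be non-empty.")
  }
  if (m > length(all_scores)) {
    abort("member set larger than the measured-gene pool.")
  }
  check_scalar_number(n_perm, "n_perm", lower = 1)
  obs <- quartile_mean(member_scores, quartile_type)
  null <- with_seed(seed, permutation_null(all_scores, m, n_perm, quartile_type))
  sc <- sum(obs > null) / n_perm
  tibble(relative_score = sc, relative_level = relative_level(sc),
         n_members = m, n_perm = as.integer(n_perm))
}

permutation_null <- function(all_scores, m, n_perm, quartile_type = 7) {
  n <- length(all_scores)
  if (quartile_type == 7) {
    vapply(seq_len(n_perm),
           function(i) quartile_mean7(all_scores[sample.int(n, m)]),
           numeric(1))
  } else {
    vapply(seq_len(n_perm),
           function(i) quartile_mean(all_scores[sample.int(n, m)], quartile_type),
           numeric(1))
  }
}

#' Absolute and relative scores for a whole collection
#'
#' Runs [pathway_absolute_score()] and [pathway_relative_score()] on the
#' measured member genes of every set. Member genes default to each set's
#' intersection with `members_of` (normally the DPG gene list); sets without
#' measured members are flagged with `NA` scores. Permutation nulls are
#' shared between sets of equal member count (the null depends only on the
#' count), which keeps ten-thousand-permutation runs cheap.
#'
#' @param collection Collection tibble.
#' @param de Differential-expression tibble from [moderated_de()].
#' @param members_of Optional gene universe to intersect each set with (e.g.
#'   DPG genes); `NULL` scores all measured set members.
#' @param n_perm Permutations per set.
#' @param seed Optional seed.
#' @param quartile_type Quantile convention.
#' @return Tibble with one row per set: `set_name`, `n_members_measured`,
#'   `absolute_score`, `absolute_level`, `relative_score`, `relative_level`.
#' @export
score_pathways <- function(collection, de, members_of = NULL, n_perm = 10000,
                           seed = NULL, quartile_type = 7) {
  collection <- as_collection(collection)
  pool <- setNames(de$score, de$gene_id)
  member_scores <- lapply(collection$genes, function(g) {
    if (!is.null(members_of)) {
      g <- intersect(g, members_of)
    }
    pool[intersect(g, names(pool))]
  })
  sizes <- lengths(member_scores)
  with_seed(seed, {
    nulls <- lapply(unique(sizes[sizes > 0]), function(m) {
      permutation_null(unname(pool), m, n_perm, quartile_type)
    })
    names(nulls) <- as.character(unique(sizes[sizes > 0]))
    rows <- lapply(seq_along(member_scores), function(i) {
      ms <- member_scores[[i]]
      if (length(ms) == 0L) {
        return(tibble(set_name = collection$set_name[i],
                      n_members_measured = 0L,
                      absolute_score = NA_real_, absolute_level = NA_integer_,
                      relative_score = NA_real_, relative_level = NA_integer_))
      }
      obs <- quartile_mean(ms, quartile_type)
      sc <- sum(obs > nulls[[as.character(length(ms))]]) / n_perm
      tibble(set_name = collection$set_name[i],
             n_members_measured = length(ms),
             absolute_score = obs, absolute_level = absolute_level(obs),
             relative_score = sc, relative_level = relative_level(sc))
    })
    out <- bind_rows(rows)
    attr(out, "n_perm") <- as.integer(n_perm)
    attr(out, "quartile_type") <- quartile_type
    out
  })
}
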