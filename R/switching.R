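#' Split samples into regulator-low and regulator-high groups
#'
#' @param regulator_expr named numeric vector of per-sample regulator
#'   expression.
#' @param method `"median"` (below-median samples are low; values equal to
#'   the median join the low group), `"threshold"` (explicit cut:
#'   `expr < threshold` is low), or `"preset"` (an explicit sample-to-group
#'   mapping taken verbatim, for published group assignments).
#' @param threshold numeric cut for `method = "threshold"`.
#' @param preset named character vector (`"low"`/`"high"`) for
#'   `method = "preset"`.
#' @return factor with levels `low`, `high`, named by sample. Errors if
#'   either group ends up with fewer than 2 samples.
#' @export
split_by_regulator <- function(regulator_expr,
                               method = c("median", "threshold", "preset"),
                               threshold = NULL, preset = NULL) {
  method <- match.arg(method)
  if (is.null(names(regulator_expr)) && method != "preset")
    names(regulator_expr) <- paste0("s", seq_along(regulator_expr))
  g <- switch(method,
    median = {
      med <- stats::median(regulator_expr)
      ifelse(regulator_expr <= med & regulator_expr < max(regulator_expr),
             "low", "high")
    },
    threshold = {
      if (is.null(threshold)) stop("method 'threshold' needs a threshold")
      ifelse(regulator_expr < threshold, "low", "high")
    },
    preset = {
      if (is.null(preset) || is.null(names(preset)))
        stop("method 'preset' needs a named sample-to-group mapping")
      if (!all(preset %in% c("low", "high")))
        stop("preset groups must be 'low' or 'high'")
      as.character(preset)
    })
  nm <- if (method == "preset") names(preset) else names(regulator_expr)
  out <- factor(g, levels = c("low", "high"))
  names(out) <- nm
  if (any(table(out) < 2L))
    stop("each group needs at least 2 samples (got ",
         paste(table(out), collapse = "/"), "); no usable separation")
  out
}

# Orient each gene's isoform pair: isoform1 is the isoform with the higher
# mean fraction among regulator-high samples (median split of the regulator),
# so that a positive delta_r reads "isoform1 tracks the regulator".
.orient_pair <- function(f, high_idx) {
  m <- rowMeans(f[, high_idx, drop = FALSE], na.rm = TRUE)
  if (!is.na(m[2L]) && (is.na(m[1L]) || m[2L] > m[1L])) c(2L, 1L) else c(1L, 2L)
}

#' Correlation-difference isoform-switch scores
#'
#' The discovery statistic of the pipeline. For each two-isoform gene, the
#' Pearson correlation of the regulator's expression with the second
#' isoform's relative frequency is subtracted from its correlation with the
#' first isoform's frequency: `delta_r = r1 - r2`, in \[-2, 2\]. Isoform 1
#' of each pair is oriented as the isoform favoured in regulator-high
#' samples, so true regulator-coupled switches score near +2 and the ranking
#' is by descending `delta_r`. Genes whose summed mean isoform fractions
#' fall below `min_total_fraction` are flagged as filtered out (the
#' low-expression filter), and genes with undefined correlations (fewer than
#' 3 usable samples, or zero variance) are unscorable; neither is ranked.
#'
#' @param regulator_expr named numeric vector of regulator expression, one
#'   value per sample (same samples as `fractions`).
#' @param fractions transcript-level [expression_matrix()] with unit
#'   `"fraction"`; each scored gene must have exactly two isoforms.
#' @param min_total_fraction genes with `mean_f1 + mean_f2` below this are
#'   excluded from ranking (default 0.5).
#' @param top_k number of top-ranked genes flagged (default 20).
#' @param n_perm if > 0, adds permutation p-values (regulator permuted
#'   `n_perm` times, pooled null of `|delta_r|`) and their
#'   Benjamini-Hochberg adjustment — an extension beyond the score-based
#'   ranking, off by default.
#' @param orient_isoforms if `TRUE` (default) isoform 1 of each pair is
#'   chosen from the data as described above; if `FALSE` the pair keeps its
#'   stored row order (a fixed designation, under which `delta_r` is
#'   antisymmetric in the pair and centred at zero for null genes).
#' @return data.frame of class `switch_score`, one row per gene: isoform
#'   ids (oriented), `r1`, `r2`, `delta_r`, `mean_f1`, `mean_f2`, `n_used`,
#'   `passes_filter`, `rank` (NA when unranked), `top_k`.
#' @export
correlation_switch_scores <- function(regulator_expr, fractions,
                                      min_total_fraction = 0.5,
                                      top_k = 20L, n_perm = 0L,
                                      orient_isoforms = TRUE) {
  stopifnot(inherits(fractions, "expression_matrix"),
            fractions$unit == "fraction")
  v <- fractions$values
  if (is.null(names(regulator_expr)))
    names(regulator_expr) <- colnames(v)
  if (!identical(sort(names(regulator_expr)), sort(colnames(v))))
    stop("regulator samples and fraction matrix samples differ")
  reg <- regulator_expr[colnames(v)]
  genes <- split(seq_len(nrow(v)), fractions$gene_of[rownames(v)])
  bad <- names(genes)[lengths(genes) != 2L]
  if (length(bad))
    stop("genes without exactly two isoforms: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  med <- stats::median(reg)
  high_idx <- which(!(reg <= med & reg < max(reg)))

  score_one <- function(idx) {
    f <- v[idx, , drop = FALSE]
    if (orient_isoforms) f <- f[.orient_pair(f, high_idx), , drop = FALSE]
    usable <- !is.na(f[1L, ]) & !is.na(f[2L, ]) & !is.na(reg)
    n_used <- sum(usable)
    r1 <- r2 <- NA_real_
    if (n_used >= 3L) {
      x <- reg[usable]
      if (stats::sd(x) > 0 && stats::sd(f[1L, usable]) > 0)
        r1 <- stats::cor(x, f[1L, usable])
      if (stats::sd(x) > 0 && stats::sd(f[2L, usable]) > 0)
        r2 <- stats::cor(x, f[2L, usable])
    }
    mean_f1 <- if (n_used) mean(f[1L, usable]) else NA_real_
    mean_f2 <- if (n_used) mean(f[2L, usable]) else NA_real_
    data.frame(isoform1 = rownames(f)[1L], isoform2 = rownames(f)[2L],
               r1 = r1, r2 = r2, delta_r = r1 - r2,
               mean_f1 = mean_f1, mean_f2 = mean_f2, n_used = n_used,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(genes, score_one))
  out <- cbind(gene_id = names(genes), out)
  rownames(out) <- NULL
  out$passes_filter <- !is.na(out$mean_f1) &
    (out$mean_f1 + out$mean_f2) >= min_total_fraction
  rankable <- out$passes_filter & !is.na(out$delta_r)
  ord <- order(-out$delta_r[rankable], out$gene_id[rankable])
  out$rank <- NA_integer_
  out$rank[which(rankable)[ord]] <- seq_len(sum(rankable))
  out$top_k <- !is.na(out$rank) & out$rank <= top_k

  if (n_perm > 0L) {
    null_abs <- .delta_r_permutation_null(reg, v, fractions$gene_of, n_perm)
    obs <- abs(out$delta_r)
    out$p_perm <- vapply(obs, function(o) {
      if (is.na(o)) return(NA_real_)
      (1 + sum(null_abs >= o)) / (1 + length(null_abs))
    }, numeric(1))
    out$p_perm_bh <- stats::p.adjust(out$p_perm, method = "BH")
  }
  out <- out[order(is.na(out$rank), out$rank, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("switch_score", class(out))
  out
}

# Pooled permutation null of |delta_r| across all genes: permute the
# regulator across samples, recompute every gene's delta_r. Vectorized via
# stats::cor on the fraction matrix. Missing fractions handled pairwise.
.delta_r_permutation_null <- function(reg, v, gene_of, n_perm) {
  idx <- split(seq_len(nrow(v)), gene_of[rownames(v)])
  f1 <- v[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
  f2 <- v[vapply(idx, `[`, integer(1), 2L), , drop = FALSE]
  unlist(lapply(seq_len(n_perm), function(i) {
    p <- sample(reg)
    r1 <- suppressWarnings(
      stats::cor(p, t(f1), use = "pairwise.complete.obs"))
    r2 <- suppressWarnings(
      stats::cor(p, t(f2), use = "pairwise.complete.obs"))
    abs(as.vector(r1) - as.vector(r2))
  }))
}

#' Pooled permutation-null quantile of |delta_r|
#'
#' Permutes the regulator across samples and recomputes the absolute
#' correlation-difference score for every gene, pooling all genes and
#' permutations into one empirical null. Used for null calibration checks
#' and optional permutation p-values.
#'
#' @inheritParams correlation_switch_scores
#' @param n_perm number of regulator permutations (default 200).
#' @param prob quantile of the pooled null to return (default 0.95).
#' @return named list: `quantile` (the requested null quantile) and
#'   `null_abs` (the pooled `|delta_r|` null draws).
#' @export
delta_r_null <- function(regulator_expr, fractions, n_perm = 200L,
                         prob = 0.95) {
  stopifnot(inherits(fractions, "expression_matrix"),
            fractions$unit == "fraction")
  v <- fractions$values
  reg <- if (is.null(names(regulator_expr))) regulator_expr else
    regulator_expr[colnames(v)]
  null_abs <- .delta_r_permutation_null(reg, v, fractions$gene_of, n_perm)
  null_abs <- null_abs[!is.na(null_abs)]
  list(quantile = stats::quantile(null_abs, prob, names = FALSE),
       null_abs = null_abs)
}

#' Rank-based two-group isoform-switch score (kTSP-style)
#'
#' For each gene's isoform pair, `p_g` is the empirical probability that
#' isoform 1's relative frequency exceeds isoform 2's among samples of
#' group `g` (ties `f1 = f2` count 0.5). The score is
#' `|p_low - p_high|` in \[0, 1\]: 1 means the dominant isoform flips
#' perfectly between the groups. Depends only on within-sample orderings,
#' so it is invariant under any strictly monotone transform of the
#' fractions. This is a pairwise reimplementation of the top-scoring-pair
#' idea behind iso-kTSP for the two-isoform case.
#'
#' @param fractions transcript-level [expression_matrix()] with unit
#'   `"fraction"`, two isoforms per gene.
#' @param groups factor of `low`/`high` labels named by sample (e.g. from
#'   [split_by_regulator()]).
#' @param top_k number of top-ranked genes flagged (default 100).
#' @return data.frame of class `ktsp_score`: gene, isoform pair, `p_low`,
#'   `p_high`, `score`, `direction` (which group favours isoform 1),
#'   `rank`, `top_k`.
#' @export
ktsp_switch_scores <- function(fractions, groups, top_k = 100L) {
  stopifnot(inherits(fractions, "expression_matrix"),
            fractions$unit == "fraction")
  v <- fractions$values
  if (is.null(names(groups))) names(groups) <- colnames(v)
  groups <- groups[colnames(v)]
  if (!all(levels(factor(groups)) %in% c("low", "high")))
    stop("groups must be 'low'/'high'")
  low <- which(groups == "low"); high <- which(groups == "high")
  if (length(low) == 0L || length(high) == 0L)
    stop("both groups must be non-empty")
  genes <- split(seq_len(nrow(v)), fractions$gene_of[rownames(v)])
  if (any(lengths(genes) != 2L))
    stop("every scored gene needs exactly two isoforms")
  score_one <- function(idx) {
    f1 <- v[idx[1L], ]; f2 <- v[idx[2L], ]
    pg <- function(cols) {
      ok <- cols[!is.na(f1[cols]) & !is.na(f2[cols])]
      if (length(ok) == 0L) return(NA_real_)
      mean((f1[ok] > f2[ok]) + 0.5 * (f1[ok] == f2[ok]))
    }
    p_low <- pg(low); p_high <- pg(high)
    data.frame(isoform1 = rownames(v)[idx[1L]],
               isoform2 = rownames(v)[idx[2L]],
               p_low = p_low, p_high = p_high,
               score = abs(p_low - p_high),
               direction = if (is.na(p_low) || is.na(p_high)) NA_character_
                 else if (p_low >= p_high) "low" else "high",
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(genes, score_one))
  out <- cbind(gene_id = names(genes), out)
  rownames(out) <- NULL
  rankable <- !is.na(out$score)
  ord <- order(-out$score[rankable], out$gene_id[rankable])
  out$rank <- NA_integer_
  out$rank[which(rankable)[ord]] <- seq_len(sum(rankable))
  out$top_k <- !is.na(out$rank) & out$rank <= top_k
  out <- out[order(is.na(out$rank), out$rank, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("ktsp_score", class(out))
  out
}

#' Two-group comparison of PSI values
#'
#' Classical pooled-variance (Student) two-sample t-test of per-sample PSI
#' between regulator-low and -high groups, two-tailed. With zero pooled
#' variance and equal means the groups are indistinguishable (`t = 0`,
#' `p = 1`); with zero pooled variance and different means the statistic
#' degenerates (`t = +/-Inf`, `p = 0`) and the result is flagged.
#'
#' @param psi a `psi_record` data.frame for one event (see [compute_psi()]).
#' @param groups factor of `low`/`high` labels named by sample.
#' @return list: `mean_low`, `mean_high`, `sd_low`, `sd_high`, `n_low`,
#'   `n_high`, `t`, `p`, `degenerate`.
#' @export
compare_group_psi <- function(psi, groups) {
  stopifnot(is.data.frame(psi), all(c("sample_id", "psi") %in% names(psi)))
  if (is.null(names(groups))) stop("groups must be named by sample")
  g <- groups[psi$sample_id]
  x <- psi$psi[g == "low" & !is.na(psi$psi)]
  y <- psi$psi[g == "high" & !is.na(psi$psi)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 defined PSI values per group")
  res <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {  # zero pooled variance
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      tval <- 0; p <- 1; degen <- FALSE
    } else {
      tval <- sign(mean(x) - mean(y)) * Inf; p <- 0; degen <- TRUE
    }
  } else {
    tval <- unname(res$statistic); p <- res$p.value; degen <- FALSE
  }
  list(mean_low = mean(x), mean_high = mean(y),
       sd_low = stats::sd(x), sd_high = stats::sd(y),
       n_low = length(x), n_high = length(y),
       t = tval, p = p, degenerate = degen)
}

#' Heatmap-ready fraction table for top-ranked genes
#'
#' Relative isoform frequencies of the top-`k` ranked genes, samples ordered
#' by ascending regulator expression — the layout used to display
#' regulator-coupled switches.
#'
#' @param scores a `switch_score` table from [correlation_switch_scores()].
#' @param fractions the fraction [expression_matrix()] that was scored.
#' @param regulator_expr the regulator vector used for scoring.
#' @return data.frame: gene, isoform, role (isoform1/isoform2), then one
#'   column per sample in ascending regulator order.
#' @export
top_switch_fraction_table <- function(scores, fractions, regulator_expr) {
  sel <- scores[scores$top_k %in% TRUE, ]
  ord <- order(regulator_expr[colnames(fractions$values)])
  samples <- colnames(fractions$values)[ord]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    rbind(
      data.frame(gene_id = sel$gene_id[i], isoform = sel$isoform1[i],
                 role = "isoform1",
                 t(fractions$values[sel$isoform1[i], samples]),
                 check.names = FALSE),
      data.frame(gene_id = sel$gene_id[i], isoform = sel$isoform2[i],
                 role = "isoform2",
                 t(fractions$values[sel$isoform2[i], samples]),
                 check.names = FALSE))
  })
  do.call(rbind, rows)
}
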