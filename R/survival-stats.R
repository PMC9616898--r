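#' Stratify patients by tumor/normal fold change
#'
#' Assigns each patient to the `upregulated` stratum when the tumor-to-
#' matched-normal expression ratio of the feature reaches `threshold`
#' (boundary inclusive: a ratio of exactly 2 counts as >= 2-fold), otherwise
#' to `other`. Patients with a non-positive normal value have no defined
#' ratio and are excluded with a warning.
#'
#' @param paired data.frame with columns `patient_id`, `tumor`, `normal`.
#' @param threshold fold-change cut, default 2.
#' @return data.frame: `patient_id`, `fold_change`, `stratum` (factor
#'   `upregulated`/`other`); unevaluable patients dropped.
#' @export
stratify_by_fold_change <- function(paired, threshold = 2.0) {
  stopifnot(all(c("patient_id", "tumor", "normal") %in% names(paired)))
  bad <- paired$normal <= 0 | is.na(paired$normal) | is.na(paired$tumor)
  if (any(bad)) {
    warning(sum(bad), " patient(s) unevaluable (normal value <= 0 or ",
            "missing), excluded: ",
            paste(utils::head(paired$patient_id[bad], 5L), collapse = ", "))
    paired <- paired[!bad, , drop = FALSE]
  }
  fold <- paired$tumor / paired$normal
  data.frame(patient_id = paired$patient_id, fold_change = fold,
             stratum = factor(ifelse(fold >= threshold, "upregulated",
                                     "other"),
                              levels = c("upregulated", "other")),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function under right censoring
#' (computed via `survival::survfit`). The curve starts at 1 at time 0 and
#' is non-increasing; with no censoring it equals the empirical survival
#' function.
#'
#' @param time follow-up times (months), >= 0.
#' @param event event indicator: 1 = death observed, 0 = censored.
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `survival`, `std_err` (Greenwood), including the `t = 0` anchor row.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record")
  if (any(time < 0)) stop("negative survival times are not allowed")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv),
             std_err = c(0, fit$std.err * fit$surv))
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) via `survival::survdiff`;
#' ties are handled by simultaneous risk-set accounting at each distinct
#' event time. Symmetric in the group labels.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level factor or character vector of strata.
#' @return list: `chi_square`, `p`, `n` (per-stratum sizes),
#'   `observed`/`expected` event counts per stratum.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two strata required")
  if (any(table(group) == 0L)) stop("both strata must be non-empty")
  if (any(time < 0)) stop("negative survival times are not allowed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       n = as.vector(sd$n), observed = as.vector(sd$obs),
       expected = as.vector(sd$exp))
}

#' Threshold differential-expression filter
#'
#' Per-gene Welch (unequal-variance) t-test on `log2(x + pseudocount)`
#' between two conditions, Benjamini-Hochberg adjustment across tested
#' genes, and the strict-threshold pass rule: a gene passes iff its
#' adjusted p-value is below `p_threshold` AND its absolute log2 fold
#' change strictly exceeds `lfc_threshold` (a gene at exactly the fold-
#' change boundary fails). Fold change is mean log2 of condition B minus
#' condition A (second factor level minus first).
#'
#' @param expr numeric matrix, genes x samples, positive scale (counts or
#'   TPM).
#' @param condition two-level factor over the columns; >= 2 replicates per
#'   level required.
#' @param lfc_threshold absolute log2-fold-change threshold (strict),
#'   default 1.0.
#' @param p_threshold adjusted-p threshold (strict), default 0.01.
#' @param pseudocount added before log2, default 1.
#' @return data.frame of class `de_result`: `gene_id`, `log2_fold_change`,
#'   `p`, `p_adjusted`, `passes`.
#' @export
de_filter <- function(expr, condition, lfc_threshold = 1.0,
                      p_threshold = 0.01, pseudocount = 1) {
  expr <- as.matrix(expr)
  condition <- factor(condition)
  if (nlevels(condition) != 2L) stop("condition must have exactly two levels")
  if (any(table(condition) < 2L))
    stop("each condition needs at least 2 replicates")
  lg <- log2(expr + pseudocount)
  a <- lg[, condition == levels(condition)[1L], drop = FALSE]
  b <- lg[, condition == levels(condition)[2L], drop = FALSE]
  lfc <- rowMeans(b) - rowMeans(a)
  p <- vapply(seq_len(nrow(lg)), function(i) {
    tryCatch(stats::t.test(b[i, ], a[i, ], var.equal = FALSE)$p.value,
             error = function(e) {  # constant data in both groups
               if (isTRUE(all.equal(mean(a[i, ]), mean(b[i, ])))) 1 else 0
             })
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene_id = if (is.null(rownames(expr)))
      paste0("g", seq_len(nrow(expr))) else rownames(expr),
    log2_fold_change = lfc, p = p, p_adjusted = p_adj,
    passes = abs(lfc) > lfc_threshold & p_adj < p_threshold,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", class(out))
  out
}
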