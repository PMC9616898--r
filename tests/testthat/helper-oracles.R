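# Independent oracles: deliberately naive implementations used only to
# cross-check the package's code paths. None of these call package internals.

# Pearson correlation from the raw sum formula.
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Rank-pair score by explicit counting over samples.
brute_ktsp <- function(f1, f2, is_low) {
  count <- function(idx) {
    s <- 0
    for (i in idx) {
      if (f1[i] > f2[i]) s <- s + 1
      else if (f1[i] == f2[i]) s <- s + 0.5
    }
    s / length(idx)
  }
  abs(count(which(is_low)) - count(which(!is_low)))
}

# Product-limit estimator computed by hand.
brute_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(), survival = numeric())
  for (t in ts) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# Two-group log-rank chi-square tabulated by hand over event times.
brute_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1L]
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Independent splice-event rule checker: explicit predicate per event type
# over sorted 0-based half-open exon matrices, structurally unlike the
# package's common-prefix/suffix diff.
oracle_classify <- function(A, B, strand) {
  eq <- function(X, Y) nrow(X) == nrow(Y) && all(X == Y)
  if (eq(A, B)) return("identical")
  term_label <- function(genomic_left)
    if (genomic_left == (strand == "+")) "AF" else "AL"
  for (pr in list(list(A, B), list(B, A))) {
    X <- pr[[1L]]; Y <- pr[[2L]]
    if (nrow(X) == nrow(Y) + 1L) {
      # single-exon deletion: SE if internal, AF/AL if terminal
      for (i in seq_len(nrow(X)))
        if (eq(X[-i, , drop = FALSE], Y)) {
          if (i > 1L && i < nrow(X)) return("SE")
          return(term_label(i == 1L))
        }
      # merge of two consecutive exons into their span: RI
      for (i in seq_len(nrow(X) - 1L)) {
        M <- rbind(X[seq_len(i - 1L), , drop = FALSE],
                   c(X[i, 1L], X[i + 1L, 2L]),
                   X[setdiff(seq_len(nrow(X)), seq_len(i + 1L)), ,
                     drop = FALSE])
        if (eq(M, Y)) return("RI")
      }
    }
  }
  if (nrow(A) == nrow(B)) {
    d <- which(A[, 1L] != B[, 1L] | A[, 2L] != B[, 2L])
    if (length(d) == 1L) {
      i <- d; nA <- nrow(A); a <- A[i, ]; b <- B[i, ]
      share_l <- a[1L] == b[1L]; share_r <- a[2L] == b[2L]
      if (share_l && !share_r) {
        if (i < nA) return(if (strand == "+") "A5" else "A3")
        return(term_label(FALSE))
      }
      if (share_r && !share_l) {
        if (i > 1L) return(if (strand == "+") "A3" else "A5")
        return(term_label(TRUE))
      }
      if (i == 1L && nA > 1L) return(term_label(TRUE))
      if (i == nA && nA > 1L) return(term_label(FALSE))
      if (i > 1L && i < nA && (a[2L] <= b[1L] || b[2L] <= a[1L]))
        return("MX")
      return("complex")
    }
  }
  "complex"
}

# All exon chains of 1..max_exons exons whose boundaries come from a strict
# grid of `n_boundaries` points: each chain picks 2k distinct boundaries.
enumerate_chains <- function(n_boundaries = 6L, max_exons = 3L) {
  bounds <- seq_len(n_boundaries) * 10
  chains <- list()
  for (k in seq_len(max_exons)) {
    if (2L * k > n_boundaries) break
    picks <- utils::combn(bounds, 2L * k, simplify = FALSE)
    for (p in picks)
      chains[[length(chains) + 1L]] <-
        matrix(p, ncol = 2L, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  }
  chains
}

make_tm <- function(exons, strand = "+", gene = "g", tx = "t",
                    chrom = "chr1") {
  transcript_model(gene, tx, chrom, strand, exons)
}
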