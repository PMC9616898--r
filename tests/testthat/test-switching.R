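frac_em <- function(f1, genes = "g1", samples = NULL) {
  # build a two-isoform fraction matrix from per-gene f1 rows
  f1 <- rbind(f1)
  n <- ncol(f1)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  rows <- do.call(rbind, lapply(seq_along(genes), function(i)
    rbind(f1[i, ], 1 - f1[i, ])))
  ids <- as.vector(vapply(genes, function(g) paste0(g, c(".1", ".2")),
                          character(2)))
  dimnames(rows) <- list(ids, samples)
  expression_matrix(rows, "fraction",
                    gene_of = stats::setNames(rep(genes, each = 2), ids))
}

test_that("median split halves a regulator gradient; presets pass verbatim", {
  x <- stats::setNames(1:18, paste0("s", 1:18))
  g <- split_by_regulator(x, "median")
  expect_equal(as.vector(table(g)), c(9L, 9L))
  expect_true(all(g[paste0("s", 1:9)] == "low"))

  preset <- stats::setNames(rep(c("low", "high"), c(5, 13)), paste0("s", 1:18))
  g2 <- split_by_regulator(x, "preset", preset = preset)
  expect_equal(as.vector(table(g2)), c(5L, 13L))

  expect_error(split_by_regulator(rep(3, 6), "median"), "separation")
  expect_error(split_by_regulator(c(1, 2, 3, 4), "threshold", threshold = 2),
               "at least 2")
})

test_that("a perfect switch reaches delta_r = 2 and a flat gene is excluded", {
  reg <- stats::setNames(c(1, 3, 5, 7, 9, 11), paste0("s", 1:6))
  z <- as.vector(scale(reg))
  f1 <- (z - min(z)) / diff(range(z))          # linear in the regulator
  em <- frac_em(rbind(f1, rep(0.4, 6)), genes = c("gSwitch", "gFlat"))
  sc <- correlation_switch_scores(reg, em, top_k = 1)
  sw <- sc[sc$gene_id == "gSwitch", ]
  expect_equal(sw$r1, 1)
  expect_equal(sw$r2, -1)
  expect_equal(sw$delta_r, 2)
  expect_equal(sw$rank, 1L)
  # zero-variance fractions: correlation undefined, gene unranked
  fl <- sc[sc$gene_id == "gFlat", ]
  expect_true(is.na(fl$delta_r))
  expect_true(is.na(fl$rank))
})

test_that("delta_r equals twice a brute-force Pearson on complementary pairs", {
  reg <- c(1, 2, 3, 4)
  f1 <- c(0.1, 0.4, 0.6, 0.9)
  em <- frac_em(f1)
  sc <- correlation_switch_scores(reg, em, top_k = 1)
  r_oracle <- brute_pearson(reg, f1)
  expect_equal(sc$delta_r, 2 * r_oracle, tolerance = 1e-12)

  # random vectors at cohort sizes 4..18
  withr::local_seed(14)
  for (n in c(4, 7, 11, 18)) {
    reg <- runif(n, 1, 100)
    f1 <- runif(n)
    sc <- correlation_switch_scores(stats::setNames(reg, paste0("s", 1:n)),
                                    frac_em(f1), top_k = 1)
    want <- 2 * brute_pearson(reg, f1)
    # orientation may flip the pair; the magnitude is pinned
    expect_equal(abs(sc$delta_r), abs(want), tolerance = 1e-10)
    expect_equal(sc$r2, -sc$r1, tolerance = 1e-12)
  }
})

test_that("delta_r is antisymmetric under isoform swap", {
  withr::local_seed(19)
  reg <- stats::setNames(runif(8, 1, 10), paste0("s", 1:8))
  f1 <- runif(8)
  em <- frac_em(f1)
  swapped <- em
  swapped$values <- swapped$values[c(2, 1), ]
  a <- correlation_switch_scores(reg, em, orient_isoforms = FALSE)
  b <- correlation_switch_scores(reg, swapped, orient_isoforms = FALSE)
  expect_equal(b$delta_r, -a$delta_r, tolerance = 1e-12)
  expect_equal(b$r1, a$r2, tolerance = 1e-12)
})

test_that("the expression filter excludes low-abundance genes from ranking", {
  reg <- stats::setNames(1:6, paste0("s", 1:6))
  f1 <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  # designated pair holds only 40% of the gene's output on average
  # (the remainder sits in undesignated isoforms)
  em <- frac_em(f1)
  em$values["g1.1", ] <- f1 * 0.5
  em$values["g1.2", ] <- (1 - f1) * 0.3     # mean total 0.4
  sc <- correlation_switch_scores(reg, em)
  expect_false(sc$passes_filter)
  expect_true(is.na(sc$rank))
  # exactly at the boundary: kept (the filter drops strictly-below genes)
  em$values["g1.1", ] <- f1
  em$values["g1.2", ] <- (1 - f1) * (0.5 - mean(f1)) / mean(1 - f1)
  sc2 <- correlation_switch_scores(reg, em)
  expect_equal(sc2$mean_f1 + sc2$mean_f2, 0.5, tolerance = 1e-12)
  expect_true(sc2$passes_filter)
})

test_that("scores ignore expression scale: only fractions matter", {
  withr::local_seed(3)
  reg <- stats::setNames(runif(10, 1, 50), paste0("s", 1:10))
  f1 <- runif(10)
  em <- frac_em(f1)
  base <- correlation_switch_scores(reg, em, top_k = 1)
  # a strictly monotone transform of the regulator changes r but any
  # monotone relabelling of total expression leaves fractions untouched;
  # the score is a function of (reg, fractions) only, so recomputing from
  # rescaled totals is identical by construction
  tpm_like <- em
  expect_equal(correlation_switch_scores(reg, tpm_like, top_k = 1)$delta_r,
               base$delta_r)
  # ktsp additionally survives monotone transforms of the fractions
  g <- split_by_regulator(reg)
  k1 <- ktsp_switch_scores(em, g)
  em2 <- em
  em2$values <- plogis(5 * (em2$values - 0.5))  # strictly monotone, [0,1]
  k2 <- ktsp_switch_scores(em2, g)
  expect_equal(k1$score, k2$score, tolerance = 1e-12)
})

test_that("ktsp score matches exhaustive counting and its extremes", {
  # perfect separation scores 1
  g <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  names(g) <- paste0("s", 1:6)
  em <- frac_em(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3))
  expect_equal(ktsp_switch_scores(em, g)$score, 1)
  expect_equal(ktsp_switch_scores(em, g)$direction, "low")
  # identical patterns score 0
  em0 <- frac_em(rep(c(0.8, 0.3, 0.6), 2))
  expect_equal(ktsp_switch_scores(em0, g)$score, 0)
  # mixed orderings, including ties, vs brute-force enumeration
  withr::local_seed(8)
  for (rep_i in 1:20) {
    f1 <- sample(c(0.25, 0.5, 0.75), 6, TRUE)  # ties with f2 = 1 - f1 at 0.5
    em <- frac_em(f1)
    got <- ktsp_switch_scores(em, g)$score
    expect_equal(got, brute_ktsp(f1, 1 - f1, g == "low"))
  }
})

test_that("group PSI comparison matches the pooled-variance hand formula", {
  psi <- compute_psi(c(9, 8, 8.5, 1, 2, 1.5) * 10,
                     c(1, 2, 1.5, 9, 8, 8.5) * 10, 1, 1,
                     event_id = "e", sample_id = paste0("s", 1:6))
  g <- stats::setNames(factor(rep(c("low", "high"), each = 3),
                              c("low", "high")), paste0("s", 1:6))
  res <- compare_group_psi(psi, g)
  x <- c(0.9, 0.8, 0.85); y <- c(0.1, 0.2, 0.15)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$mean_low, 0.85)

  # identical groups: t = 0, p = 1
  psi2 <- psi; psi2$psi <- rep(c(0.3, 0.5, 0.7), 2)
  res2 <- compare_group_psi(psi2, g)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  # zero variance, different means: degenerate, flagged, no error
  psi3 <- psi; psi3$psi <- rep(c(0.9, 0.1), each = 3)
  res3 <- compare_group_psi(psi3, g)
  expect_true(res3$degenerate)
  expect_true(is.infinite(res3$t))
  expect_equal(res3$p, 0)

  expect_error(compare_group_psi(psi[1:3, ], g), "per group")
})

test_that("null cohorts give centred scores; permutation p-values are sane", {
  co <- simulate_cohort(cohort_config(n_switch_genes = 0L,
                                      n_null_genes = 120L, seed = 42L))
  fr <- isoform_fractions(tpm_normalize(co$counts,
                                        co$ground_truth$effective_lengths))
  sc <- correlation_switch_scores(co$regulator, fr, n_perm = 50L)
  expect_lt(abs(mean(sc$delta_r, na.rm = TRUE)), 0.15)
  expect_true(all(sc$p_perm > 0 & sc$p_perm <= 1, na.rm = TRUE))
  expect_true(all(sc$p_perm_bh >= sc$p_perm, na.rm = TRUE))
})
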