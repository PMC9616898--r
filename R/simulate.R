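#' Configuration for a synthetic switch-discovery cohort
#'
#' Defaults emulate the statistical design the scoring pipeline assumes:
#' an 18-sample panel with a continuous regulator expression gradient,
#' 20 regulator-coupled switch genes among 2000 two-isoform genes, bulk
#' RNA-seq negative-binomial count noise, and cassette-exon junction
#' coverage of a few dozen reads per sample.
#'
#' @param n_samples cohort size (>= 4), default 18.
#' @param n_switch_genes regulator-coupled genes, default 20.
#' @param n_null_genes regulator-independent genes, default 1980.
#' @param regulator_log_mean,regulator_log_sd log-normal parameters of the
#'   regulator's TPM across samples.
#' @param switch_slope logistic link strength beta between the standardized
#'   (log-scale) regulator and the inclusion-isoform fraction, default 4.
#' @param switch_center link midpoint on the standardized regulator scale,
#'   default 0.
#' @param gene_expression_log_mean,gene_expression_log_sd log-normal
#'   parameters of per-gene total expression.
#' @param nb_dispersion negative-binomial dispersion (counts have variance
#'   `mu + dispersion * mu^2`), > 0, default 0.1.
#' @param junction_depth_mean mean junction read depth per event and
#'   sample, default 50.
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 18L, n_switch_genes = 20L,
                          n_null_genes = 1980L,
                          regulator_log_mean = log(50),
                          regulator_log_sd = 1,
                          switch_slope = 4, switch_center = 0,
                          gene_expression_log_mean = log(500),
                          gene_expression_log_sd = 1,
                          nb_dispersion = 0.1,
                          junction_depth_mean = 50, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_switch_genes = as.integer(n_switch_genes),
              n_null_genes = as.integer(n_null_genes),
              regulator_log_mean = regulator_log_mean,
              regulator_log_sd = regulator_log_sd,
              switch_slope = switch_slope, switch_center = switch_center,
              gene_expression_log_mean = gene_expression_log_mean,
              gene_expression_log_sd = gene_expression_log_sd,
              nb_dispersion = nb_dispersion,
              junction_depth_mean = junction_depth_mean,
              seed = as.integer(seed))
  if (cfg$n_samples < 4L) stop("n_samples must be >= 4")
  if (cfg$n_switch_genes < 0L || cfg$n_null_genes < 0L)
    stop("gene counts must be >= 0")
  if (cfg$n_switch_genes + cfg$n_null_genes == 0L)
    stop("degenerate config: zero genes")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  class(cfg) <- "cohort_config"
  cfg
}

# Per-gene substream seed: a fixed affine counter keyed on the gene index,
# so adding genes never reshuffles the draws of existing ones.
.substream_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483629)
}

#' Simulate a regulator-graded isoform-switch cohort
#'
#' Generates the inputs every downstream stage consumes, plus ground truth:
#' \itemize{
#'   \item a regulator gene with log-normal TPM across samples;
#'   \item two-isoform genes, each an inclusion isoform (3 exons, middle
#'     72-nt cassette) and a skipping isoform (cassette absent) on its own
#'     reference contig, so the pair classifies as SE;
#'   \item for switch genes, the inclusion fraction follows a logistic link
#'     `f1(s) = plogis(beta * (z_s - center))` on the standardized
#'     log-regulator `z`; null genes have a constant fraction drawn once
#'     from U(0.2, 0.8);
#'   \item transcript counts `NB(mean = expr * fraction * length/1000,
#'     dispersion)`;
#'   \item cassette junction counts: total depth Poisson, split between the
#'     two inclusion junctions and the one skipping junction so that the
#'     length-normalized PSI estimator is centred on `f1`.
#' }
#' Deterministic under a fixed seed; each gene draws from its own counter-
#' based substream.
#'
#' @param config a [cohort_config()].
#' @return list: `counts` (transcript-level count [expression_matrix()]),
#'   `models` (named list of [transcript_model()]), `junctions`
#'   (data.frame: event_id, sample_id, inclusion, exclusion), `metadata`
#'   (data.frame: sample_id, group (median split of the regulator),
#'   regulator_tpm), `regulator` (named TPM vector), `ground_truth` (list:
#'   switch_gene_ids, switch_slope, switch_center, true_f1 matrix,
#'   null_fractions).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  samples <- sprintf("S%02d", seq_len(n))
  set.seed(config$seed)
  reg <- stats::rlnorm(n, config$regulator_log_mean, config$regulator_log_sd)
  names(reg) <- samples
  z <- as.vector(scale(log(reg)))

  n_genes <- config$n_switch_genes + config$n_null_genes
  genes <- sprintf("G%04d", seq_len(n_genes))
  is_switch <- seq_len(n_genes) <= config$n_switch_genes
  exon_len <- c(200L, 72L, 300L)  # cassette is the 72-nt middle exon
  len_inc <- sum(exon_len); len_exc <- sum(exon_len[-2L])

  true_f1 <- matrix(NA_real_, n_genes, n, dimnames = list(genes, samples))
  counts <- matrix(0, 2L * n_genes, n)
  models <- vector("list", 2L * n_genes)
  tx_ids <- character(2L * n_genes)
  gene_of <- character(2L * n_genes)
  junc <- vector("list", n_genes)
  null_frac <- rep(NA_real_, n_genes); names(null_frac) <- genes

  for (i in seq_len(n_genes)) {
    set.seed(.substream_seed(config$seed, i))
    g <- genes[i]
    expr <- stats::rlnorm(1L, config$gene_expression_log_mean,
                          config$gene_expression_log_sd)
    if (is_switch[i]) {
      f1 <- stats::plogis(config$switch_slope * (z - config$switch_center))
    } else {
      null_frac[i] <- stats::runif(1L, 0.2, 0.8)
      f1 <- rep(null_frac[i], n)
    }
    true_f1[i, ] <- f1
    mu1 <- expr * f1 * len_inc / 1000
    mu2 <- expr * (1 - f1) * len_exc / 1000
    size <- 1 / config$nb_dispersion
    c1 <- stats::rnbinom(n, mu = mu1, size = size)
    c2 <- stats::rnbinom(n, mu = mu2, size = size)
    j1 <- 2L * i - 1L; j2 <- 2L * i
    counts[j1, ] <- c1; counts[j2, ] <- c2
    tx_ids[j1] <- paste0(g, ".inc"); tx_ids[j2] <- paste0(g, ".exc")
    gene_of[j1] <- gene_of[j2] <- g
    chrom <- paste0("ctg_", g)
    ex_inc <- rbind(c(1000, 1200), c(1400, 1472), c(1600, 1900))
    models[[j1]] <- transcript_model(g, tx_ids[j1], chrom, "+", ex_inc)
    models[[j2]] <- transcript_model(g, tx_ids[j2], chrom, "+",
                                     ex_inc[-2L, , drop = FALSE])
    # junction reads: two inclusion junctions vs one skipping junction
    depth <- stats::rpois(n, config$junction_depth_mean)
    p_inc <- 2 * f1 / (2 * f1 + (1 - f1))
    inc <- stats::rbinom(n, depth, p_inc)
    junc[[i]] <- data.frame(event_id = paste0(g, ".SE"), sample_id = samples,
                            inclusion = inc, exclusion = depth - inc,
                            stringsAsFactors = FALSE)
  }
  dimnames(counts) <- list(tx_ids, samples)
  names(models) <- tx_ids
  names(gene_of) <- tx_ids
  em <- expression_matrix(counts, unit = "count", gene_of = gene_of,
                          feature_level = "transcript")
  group <- split_by_regulator(reg, method = "median")
  metadata <- data.frame(sample_id = samples,
                         group = as.character(group[samples]),
                         regulator_tpm = unname(reg),
                         stringsAsFactors = FALSE)
  list(counts = em, models = models,
       junctions = do.call(rbind, junc), metadata = metadata,
       regulator = reg,
       ground_truth = list(
         switch_gene_ids = genes[is_switch],
         switch_slope = config$switch_slope,
         switch_center = config$switch_center,
         true_f1 = true_f1,
         null_fractions = null_frac[!is_switch],
         effective_lengths = stats::setNames(
           rep(c(len_inc, len_exc), n_genes), tx_ids)))
}

#' Simulate a paired tumor/normal cohort with survival outcomes
#'
#' Emulates a fold-change-stratified overall-survival design: each patient
#' has matched tumor and normal expression of one surrogate feature; the
#' tumor/normal log2 ratio is Gaussian, tuned so roughly a third of
#' patients reach the 2-fold up-regulation boundary. Event times are
#' exponential with baseline rate `baseline_hazard`, multiplied by
#' `hazard_ratio` for patients at or above `fold_threshold`; censoring is
#' independent uniform on (0, `censor_max`) (set `censor_max = Inf` for no
#' censoring). Times are in months; `event = 1` means death observed.
#'
#' @param n_patients number of patients (>= 2), default 37.
#' @param fold_threshold tumor/normal ratio defining the up-regulated
#'   stratum (inclusive), default 2.
#' @param hazard_ratio multiplicative hazard of the up-regulated stratum
#'   (> 0); 1 is the null.
#' @param seed integer RNG seed.
#' @param baseline_hazard events per month for the reference stratum;
#'   default `log(2)/40` (40-month median survival).
#' @param censor_max upper bound of the uniform censoring time, months.
#' @param log2fc_mean,log2fc_sd distribution of the tumor/normal log2 ratio.
#' @return data.frame: `patient_id`, `tumor`, `normal`, `fold_change`,
#'   `stratum`, `time`, `event`; attribute `hazard_ratio` records the
#'   ground truth.
#' @export
simulate_survival_cohort <- function(n_patients = 37L, fold_threshold = 2.0,
                                     hazard_ratio = 1.0, seed = 1L,
                                     baseline_hazard = log(2) / 40,
                                     censor_max = 120,
                                     log2fc_mean = 0.3, log2fc_sd = 1.5) {
  if (n_patients < 2L) stop("need at least 2 patients")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  set.seed(as.integer(seed))
  normal <- stats::rlnorm(n_patients, log(20), 0.5)
  fold <- 2 ^ stats::rnorm(n_patients, log2fc_mean, log2fc_sd)
  tumor <- normal * fold
  up <- fold >= fold_threshold
  rate <- baseline_hazard * ifelse(up, hazard_ratio, 1)
  t_event <- stats::rexp(n_patients, rate)
  t_cens <- if (is.finite(censor_max))
    stats::runif(n_patients, 0, censor_max) else rep(Inf, n_patients)
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    tumor = tumor, normal = normal, fold_change = fold,
    stratum = factor(ifelse(up, "upregulated", "other"),
                     levels = c("upregulated", "other")),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE)
  attr(out, "hazard_ratio") <- hazard_ratio
  out
}
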