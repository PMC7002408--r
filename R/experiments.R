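## Seeded Monte-Carlo experiments used both by the test suite and by
## scripts/acceptance.R: null calibration of the three test layers,
## sweep-detection power on an implanted sweep, and recovery of programmed
## phenotype effect sizes. Problem sizes are desk-scale analogues of the
## study design (three populations of 40 diploids; RIL/F2 line counts and
## effect sizes matching the printed association tables).

## Independent replicate seeds derived from one master seed, so different
## master seeds give non-overlapping replicate streams.
derive_rep_seeds <- function(seed, n_reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

#' Null calibration of the HKA-style test
#'
#' Simulates fully neutral three-population genomes and measures, per
#' replicate, the fraction of genes with HKA p below `alpha`. Drift is set
#' high (F = 0.6 for all populations) so that fixed-site counts are
#' non-degenerate genome-wide -- with weak drift essentially no site exceeds
#' the FST > 0.9 fixation cutoff and the 2x2 test is undefined.
#'
#' @param n_reps Number of replicates.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @param n_sites,n_genes,n_diploids Problem size per replicate.
#' @return List `rate` (mean per-replicate rejection fraction), `per_rep`,
#'   `n_reps`.
#' @export
hka_null_calibration <- function(n_reps = 200, alpha = 0.05, seed = 1L,
                                 n_sites = 5000L, n_genes = 50L,
                                 n_diploids = 20L) {
  model <- population_model(n_diploids_per_pop = n_diploids,
                            drift_F_per_pop = c(0.6, 0.6, 0.6),
                            chrom_length_bp = 1e6, n_sites = n_sites)
  genes <- tiling_genes("chr09", model$chrom_length_bp, n_genes, gene_length = 4000L)
  rep_seeds <- derive_rep_seeds(seed, n_reps)
  per_rep <- vapply(seq_len(n_reps), function(r) {
    gm <- simulate_three_pop_genotypes(model, NULL, seed = rep_seeds[r])
    gs <- hka_scan(gene_fst_and_counts(gm, genes, model$pop_labels[1]))
    mean(gs$hka_p < alpha, na.rm = TRUE)
  }, numeric(1))
  list(rate = mean(per_rep), per_rep = per_rep, n_reps = n_reps)
}

#' Null calibration of the KS distance-decay test
#'
#' Neutral genomes, focal position at the chromosome center: per replicate,
#' the first distance bin is KS-tested against the genome background and the
#' rejection indicator recorded. Ties in the discrete frequency support make
#' the asymptotic test conservative; the rate is compared against the
#' nominal level with binomial Monte-Carlo tolerance.
#'
#' @inheritParams hka_null_calibration
#' @return List `rate`, `per_rep` (logical), `n_reps`.
#' @export
ks_null_calibration <- function(n_reps = 200, alpha = 0.05, seed = 1L,
                                n_sites = 5000L, n_diploids = 20L) {
  model <- population_model(n_diploids_per_pop = n_diploids,
                            drift_F_per_pop = c(0.2, 0.2, 0.5),
                            chrom_length_bp = 1e6, n_sites = n_sites)
  focal <- model$chrom_length_bp %/% 2L
  rep_seeds <- derive_rep_seeds(seed, n_reps)
  per_rep <- vapply(seq_len(n_reps), function(r) {
    gm <- simulate_three_pop_genotypes(model, NULL, seed = rep_seeds[r])
    pol <- suppressMessages(polarize_derived(gm, model$pop_labels[1], model$pop_labels[3]))
    spec <- distance_binned_spectra(pol, focal)
    bg <- background_derived_freqs(pol, focal)
    ks <- ks_decay_test(spec, bg)
    p1 <- ks$bins$ks_p[1]
    !is.na(p1) && p1 < alpha
  }, logical(1))
  list(rate = mean(per_rep), per_rep = per_rep, n_reps = n_reps)
}

#' Type-I error of the pooled t-test association
#'
#' Null Gaussian phenotypes, two groups of `n_per_group`: rejection rate at
#' `alpha` over `n_reps` replicates (exact under the null, so the rate is a
#' direct calibration check of the testing path).
#'
#' @inheritParams hka_null_calibration
#' @param n_per_group Group size.
#' @return List `rate`, `n_reps`.
#' @export
ttest_null_calibration <- function(n_reps = 2000, alpha = 0.05, seed = 1L,
                                   n_per_group = 20L) {
  set.seed(seed)
  rej <- vapply(seq_len(n_reps), function(r) {
    res <- t_test_association(stats::rnorm(n_per_group), stats::rnorm(n_per_group))
    res$p < alpha
  }, logical(1))
  list(rate = mean(rej), n_reps = n_reps)
}

#' Sweep-detection power experiment
#'
#' Per replicate: a three-population genome with one implanted strong sweep
#' (w0 = 0.9, decay 25 kb, high-frequency floor 0.95) centered in a known
#' gene; the scan pipeline's candidate call (PBS top `pbs_quantile` and HKA
#' p < `hka_alpha`) is checked for that gene, and the AFS distance-decay
#' Spearman correlation around the focal site is recorded.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param chrom_length_bp,n_sites,n_diploids,n_genes Genome scale (defaults:
#'   5 Mb, 50k SNPs, 40 diploids per population, 250 genes of 4 kb).
#' @param thresholds A [scan_thresholds()].
#' @return List `detection_rate`, `decay_negative_rate`, `per_rep` (data
#'   frame `detected`, `spearman_rho`), `n_reps`.
#' @export
sweep_detection_experiment <- function(n_reps = 50, seed = 1L,
                                       chrom_length_bp = 5e6, n_sites = 5e4,
                                       n_diploids = 40L, n_genes = 250L,
                                       thresholds = scan_thresholds()) {
  model <- population_model(n_diploids_per_pop = n_diploids,
                            drift_F_per_pop = c(0.2, 0.2, 0.5),
                            chrom_length_bp = chrom_length_bp, n_sites = n_sites)
  genes <- tiling_genes("chr09", chrom_length_bp, n_genes, gene_length = 4000L)
  swept_gene <- genes$gene_id[n_genes %/% 2L]
  focal <- (genes$start[n_genes %/% 2L] + genes$end[n_genes %/% 2L]) %/% 2L
  sweep <- sweep_config(focal_position_bp = focal, target_pop = model$pop_labels[1],
                        intensity_w0 = 0.9, decay_length_bp = 25000,
                        high_freq_floor = 0.95)
  rep_seeds <- derive_rep_seeds(seed, n_reps)
  per_rep <- lapply(seq_len(n_reps), function(r) {
    gm <- simulate_three_pop_genotypes(model, sweep, seed = rep_seeds[r])
    gs <- hka_scan(gene_fst_and_counts(gm, genes, model$pop_labels[1],
                                       fixation_fst_cutoff = thresholds$fixation_fst_cutoff))
    cand <- sweep_candidates(gs, thresholds)
    pol <- suppressMessages(polarize_derived(gm, model$pop_labels[1], model$pop_labels[3]))
    spec <- distance_binned_spectra(pol, focal)
    bg <- background_derived_freqs(pol, focal)
    ks <- ks_decay_test(spec, bg)
    data.frame(detected = swept_gene %in% cand$gene_id,
               spearman_rho = ks$decay$spearman_rho)
  })
  per_rep <- do.call(rbind, per_rep)
  list(detection_rate = mean(per_rep$detected),
       decay_negative_rate = mean(per_rep$spearman_rho < 0, na.rm = TRUE),
       per_rep = per_rep, n_reps = n_reps)
}

#' Effect-size recovery experiment
#'
#' Programs a single causal locus with homozygote contrasts matching the
#' printed effect-size range (0.47 tillers at 40 DAG, 2.77 at 50 DAG) on a
#' panel of 135 high-homozygote and 60 low-homozygote lines (the skewed class
#' sizes of the near-isogenic F2), phenotypes each line as the mean of 8
#' plants, and measures per replicate the absolute error of the recovered
#' effect size (the t-test group-mean difference).
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param contrasts Homozygote contrasts per timepoint, tillers.
#' @param n_high,n_low Lines per homozygote class.
#' @return List with per-timepoint recovery: `recovered` (matrix reps x
#'   timepoints of estimated effects), `mean_recovered`, `within` helper.
#' @export
effect_recovery_experiment <- function(n_reps = 200, seed = 1L,
                                       contrasts = c("40DAG" = 0.47, "50DAG" = 2.77),
                                       n_high = 135L, n_low = 60L) {
  geno <- matrix(c(rep(2L, n_high), rep(0L, n_low)), ncol = 1,
                 dimnames = list(sprintf("line_%03d", seq_len(n_high + n_low)), "locus"))
  model <- phenotype_model(timepoints = names(contrasts),
                           baseline_mu = c(10, 20),
                           additive_effects = matrix(contrasts / 2, nrow = 1),
                           residual_sd = c(3.0, 6.5), plants_per_line = 8L)
  recovered <- matrix(NA_real_, n_reps, length(contrasts),
                      dimnames = list(NULL, names(contrasts)))
  rep_seeds <- derive_rep_seeds(seed, n_reps)
  for (r in seq_len(n_reps)) {
    ph <- simulate_phenotypes(geno, model, seed = rep_seeds[r])
    for (tp in names(contrasts)) {
      v <- ph[ph$timepoint == tp, ]
      vals <- stats::setNames(v$value, v$line_id)
      res <- t_test_association(vals[rownames(geno)[geno == 2]],
                                vals[rownames(geno)[geno == 0]])
      recovered[r, tp] <- res$effect_size
    }
  }
  list(recovered = recovered, mean_recovered = colMeans(recovered),
       n_reps = n_reps, contrasts = contrasts)
}
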