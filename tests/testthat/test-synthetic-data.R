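# Generators: neutral frequency law, Balding-Nichols divergence, sweep
# locality, biparental crosses, additive phenotypes.

test_that("neutral SFS law has the 1/i shape and is deterministic", {
  expect_equal(unique(draw_neutral_sfs_frequencies(50, 2, seed = 1)), 0.5)

  f <- draw_neutral_sfs_frequencies(1e5, 40, seed = 7)
  singleton_expected <- 1 / sum(1 / (1:39))
  mc_sd <- sqrt(singleton_expected * (1 - singleton_expected) / 1e5)
  expect_lt(abs(mean(f == 1 / 40) - singleton_expected), 3 * mc_sd)

  expect_identical(draw_neutral_sfs_frequencies(100, 20, seed = 3),
                   draw_neutral_sfs_frequencies(100, 20, seed = 3))
  expect_error(draw_neutral_sfs_frequencies(0, 10), "positive")
  expect_error(draw_neutral_sfs_frequencies(10, 1), "sample_chroms")
})

test_that("Balding-Nichols divergence scales with drift and matches a frequency oracle", {
  ## negligible drift -> negligible differentiation
  m0 <- population_model(drift_F_per_pop = c(0.001, 0.001, 0.001),
                         n_diploids_per_pop = 50, chrom_length_bp = 1e6,
                         n_sites = 2e4)
  gm0 <- simulate_three_pop_genotypes(m0, seed = 1)
  f0 <- pop_allele_freqs(gm0)
  expect_lt(mean(tillersweep:::fst_nei(f0[, 1], f0[, 2])), 0.01)

  ## mean FST within 20% of the brute-force GST on the true simulated
  ## frequencies (same seed), and monotone over a drift grid
  mean_fst <- vapply(c(0.05, 0.1, 0.3), function(F) {
    m <- population_model(drift_F_per_pop = c(F, F, F), n_diploids_per_pop = 50,
                          chrom_length_bp = 5e6, n_sites = 5e4)
    gm <- simulate_three_pop_genotypes(m, seed = 11)
    truth <- attr(gm, "truth")
    obs <- mean(tillersweep:::fst_nei(pop_allele_freqs(gm)[, 1],
                                      pop_allele_freqs(gm)[, 2]))
    oracle <- mean(tillersweep:::fst_nei(truth$pop_freq[, 1], truth$pop_freq[, 2]))
    if (F == 0.1) expect_lt(abs(obs - oracle) / oracle, 0.2)
    obs
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))

  ## frequencies in range; truth attribute exposed
  truth <- attr(simulate_three_pop_genotypes(
    population_model(n_sites = 1000, chrom_length_bp = 1e5,
                     n_diploids_per_pop = 10), seed = 2), "truth")
  expect_true(all(truth$pop_freq >= 0 & truth$pop_freq <= 1))
})

test_that("sweep with zero intensity is exact neutrality; distortion is local", {
  m <- population_model(n_sites = 1e4, chrom_length_bp = 2e6,
                        n_diploids_per_pop = 20)
  s0 <- sweep_config(1e6, target_pop = "upland_jap", intensity_w0 = 0,
                     decay_length_bp = 5000)
  gm_neutral <- simulate_three_pop_genotypes(m, NULL, seed = 5)
  gm_w0 <- simulate_three_pop_genotypes(m, s0, seed = 5)
  expect_identical(gm_neutral$geno, gm_w0$geno)

  ## sites > 10 * decay_length from the focus have a neutral spectrum
  s <- sweep_config(1e6, target_pop = "upland_jap", intensity_w0 = 0.8,
                    decay_length_bp = 5000)
  gm_sweep <- simulate_three_pop_genotypes(m, s, seed = 5)
  far <- abs(gm_sweep$pos - 1e6) > 10 * s$decay_length_bp
  df_sweep <- derived_allele_freqs(gm_sweep)[far, "upland_jap"]
  df_neut <- derived_allele_freqs(gm_neutral)[far, "upland_jap"]
  seg_s <- df_sweep > 0 & df_sweep < 1
  seg_n <- df_neut > 0 & df_neut < 1
  ks <- suppressWarnings(ks.test(df_sweep[seg_s], df_neut[seg_n]))
  expect_gt(ks$p.value, 0.01)

  expect_error(simulate_three_pop_genotypes(m, sweep_config(5e6)), "off-chromosome")
  expect_error(population_model(drift_F_per_pop = c(0, 0.2, 0.2)), "open interval")
})

test_that("F2 genotype classes follow the reweighted Mendelian ratio", {
  loci1 <- data.frame(name = "SNP3", position_bp = 100L)

  ## undistorted 1:2:1
  cfg <- cross_config("NIL_F2", n_individuals = 1e4, loci = loci1)
  g <- simulate_cross(cfg, seed = 1)$geno[1, ]
  props <- tabulate(g + 1L, 3L) / length(g)
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / length(g))
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))

  ## viability weights reproducing the skewed homozygote pattern (~135:60
  ## among 451): exact multinomial oracle from the renormalized weights
  w <- c(1, 0.948, 0.444)
  cfg_d <- cross_config("NIL_F2", n_individuals = 451, loci = loci1,
                        distortion_weights = list(w))
  gd <- simulate_cross(cfg_d, seed = 2)$geno[1, ]
  counts <- tabulate(gd + 1L, 3L)
  p_exp <- f2_expected_class_probs(w)
  expect_equal(sum(p_exp), 1)
  for (k in 1:3) {
    ci <- qbinom(c(0.025, 0.975), 451, p_exp[k])
    expect_gte(counts[k], ci[1])
    expect_lte(counts[k], ci[2])
  }

  expect_error(cross_config("NIL_F2", 10, loci = loci1,
                            distortion_weights = list(c(1, 0, 1))), "positive")
})

test_that("RIL_F8 lines show residual heterozygosity (1/2)^7 and linkage", {
  loci2 <- data.frame(name = c("IndelI", "SNP3"), position_bp = c(100L, 200L))
  cfg0 <- cross_config("RIL_F8", n_individuals = 2000, loci = loci2,
                       recomb_fraction = 0)
  g <- simulate_cross(cfg0, seed = 3)$geno
  expect_identical(g[1, ], g[2, ])     # complete linkage: identical classes

  het <- mean(g[1, ] == 1L)
  p_het <- (1 / 2)^7
  expect_lt(abs(het - p_het), 3 * sqrt(p_het * (1 - p_het) / ncol(g)))

  ## correlation decreases with recombination fraction
  cors <- vapply(c(0.01, 0.25, 0.5), function(r) {
    cfg <- cross_config("RIL_F8", n_individuals = 1500, loci = loci2,
                        recomb_fraction = r)
    g <- simulate_cross(cfg, seed = 4)$geno
    cor(g[1, ], g[2, ])
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("phenotype generator adds programmed effects and averages plants", {
  geno <- matrix(c(rep(0L, 40), rep(2L, 40)), ncol = 1,
                 dimnames = list(sprintf("l%02d", 1:80), "locus"))

  ## null model: no group difference beyond noise
  m0 <- phenotype_model(additive_effects = matrix(c(0, 0), nrow = 1))
  ph0 <- simulate_phenotypes(geno, m0, seed = 1)
  v <- ph0[ph0$timepoint == "40DAG", ]
  d <- mean(v$value[1:40]) - mean(v$value[41:80])
  se <- sqrt(var(v$value) * (1 / 40 + 1 / 40))
  expect_lt(abs(d), 3 * se)

  ## programmed homozygote contrast appears between the groups
  m1 <- phenotype_model(additive_effects = matrix(c(0.5, 1.385), nrow = 1))
  ph1 <- simulate_phenotypes(geno, m1, seed = 2)
  v1 <- ph1[ph1$timepoint == "50DAG", ]
  expect_lt(abs((mean(v1$value[41:80]) - mean(v1$value[1:40])) - 2.77), 1.5)

  ## averaging over more plants reduces line-level variance
  m_1p <- phenotype_model(additive_effects = matrix(c(0, 0), nrow = 1),
                          plants_per_line = 1L)
  m_8p <- phenotype_model(additive_effects = matrix(c(0, 0), nrow = 1),
                          plants_per_line = 8L)
  v1p <- simulate_phenotypes(geno, m_1p, seed = 3)
  v8p <- simulate_phenotypes(geno, m_8p, seed = 3)
  expect_gt(var(v1p$value[v1p$timepoint == "40DAG"]),
            var(v8p$value[v8p$timepoint == "40DAG"]))

  ## missing causal genotype: skipped with a warning
  geno_na <- geno; geno_na[1, 1] <- NA
  expect_warning(ph <- simulate_phenotypes(geno_na, m0, seed = 4), "skipped")
  expect_false("l01" %in% ph$line_id)

  ## determinism
  expect_identical(simulate_phenotypes(geno, m1, seed = 9),
                   simulate_phenotypes(geno, m1, seed = 9))
})
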