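# Homozygote grouping, Student's t association, conditional analysis,
# segregation distortion, Pearson correlation and the full table builder.

test_that("homozygote grouping excludes heterozygotes and flags rare sites", {
  hg <- homozygote_groups(c(a = 0L, b = 0L, c = 2L, d = 2L, e = 1L))
  expect_equal(length(hg$group0), 2L)
  expect_equal(length(hg$group2), 2L)
  expect_equal(hg$n_het, 1L)
  expect_false(hg$rare)

  ## one minor homozygote among 130: rare
  hg_rare <- homozygote_groups(c(rep(0L, 129), 2L))
  expect_true(hg_rare$rare)

  ## all homozygous for the same allele: untestable
  hg_mono <- homozygote_groups(rep(0L, 20))
  expect_true(hg_mono$untestable)
})

test_that("pooled t-test matches the textbook oracle and its summaries", {
  ## identical groups
  same <- t_test_association(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$t, same$p, same$effect_size), c(0, 1, 0))

  ## hand case: t.test and explicit pooled formula agree
  r <- t_test_association(c(10, 12, 14), c(20, 22, 24))
  o <- oracle_pooled_t(c(10, 12, 14), c(20, 22, 24))
  expect_equal(r$t, o$t)
  expect_equal(r$df, o$df)
  expect_equal(r$p, o$p)

  ## summary definitions: means 10 and 12 -> effect 2, difference 20%
  r2 <- t_test_association(c(9, 10, 11), c(11, 12, 13))
  expect_equal(r2$effect_size, 2)
  expect_equal(r2$mean_value_difference, 20)
  expect_equal(r2$pooled_variance, 1)

  ## randomized oracle equivalence and antisymmetry
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1), 10, 2); y <- rnorm(sample(3:15, 1), 11, 2)
    r <- t_test_association(x, y); o <- oracle_pooled_t(x, y)
    expect_equal(r$t, o$t)
    expect_equal(r$p, o$p)
    rswap <- t_test_association(y, x)
    expect_equal(rswap$t, -r$t)
    expect_equal(rswap$p, r$p)
    expect_equal(rswap$effect_size, r$effect_size)
    expect_equal(rswap$mean_value_difference, r$mean_value_difference)
  }

  ## Welch option matches stats::t.test without the pooled assumption
  x <- c(10, 12, 14, 19); y <- c(20, 22, 24)
  w <- t_test_association(x, y, welch = TRUE)
  ref <- t.test(x, y)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$p, ref$p.value)
  expect_equal(w$df, unname(ref$parameter))

  ## zero variance, unequal means: machine-floor p with flag
  deg <- t_test_association(c(5, 5), c(7, 7))
  expect_true(deg$degenerate)
  expect_lte(deg$p, .Machine$double.xmin)
  expect_error(t_test_association(1, c(2, 3)), "at least 2")
})

test_that("conditional association subsets on the conditioning genotype", {
  set.seed(7)
  ids <- sprintf("l%03d", 1:104)
  gA <- setNames(rep(c(0L, 2L), 52), ids)
  gB <- setNames(rep(c(0L, 0L, 2L, 2L), 26), ids)
  ph <- setNames(rnorm(104, 10), ids)
  res <- conditional_association(gA, gB, 2L, ph)
  expect_equal(res$n_conditioned, 52L)
  expect_equal(c(res$n1, res$n2), c(26L, 26L))
  expect_false(res$untestable)

  ## conditioning on an absent class: untestable
  res_none <- conditional_association(gA, gB, 1L, ph)
  expect_true(res_none$untestable)
})

test_that("conditioning on the causal locus attenuates a linked proxy's effect", {
  ## locus B is causal; locus A associates only through linkage (small r).
  ## Conditioning on B's homozygote class should shrink A's apparent effect.
  ## r = 0.3 keeps enough recombinants for the conditional groups to be
  ## testable while preserving a clear marginal LD effect
  loci <- data.frame(name = c("A", "B"), position_bp = c(100L, 200L))
  cfg <- cross_config("NIL_F2", n_individuals = 400, loci = loci,
                      recomb_fraction = 0.3)
  pm <- phenotype_model(timepoints = "50DAG", baseline_mu = 20,
                        additive_effects = matrix(c(0, 1.5), ncol = 1),
                        residual_sd = 2, plants_per_line = 8L)
  n_reps <- 100
  attenuated <- vapply(seq_len(n_reps), function(r) {
    cross <- simulate_cross(cfg, seed = 800 + r)
    geno <- t(cross$geno); colnames(geno) <- c("A", "B")
    ph <- simulate_phenotypes(geno, pm, seed = 1800 + r)
    phv <- setNames(ph$value, ph$line_id)
    gA <- setNames(geno[, "A"], rownames(geno))
    gB <- setNames(geno[, "B"], rownames(geno))
    hg <- homozygote_groups(gA, rare_cutoff = 0)
    marginal <- t_test_association(phv[hg$group0], phv[hg$group2])$effect_size
    conditional <- conditional_association(gA, gB, 2L, phv)$effect_size
    !is.na(conditional) && conditional < marginal
  }, logical(1))
  expect_gte(mean(attenuated), 0.9)
})

test_that("segregation chi-square matches hand evaluations on the printed counts", {
  ## RIL Indel I homozygote classes 32:96 against 1:1
  st <- segregation_test(c(32, 96), c(1, 1), locus = "IndelI")
  expect_equal(st$chi2, 32)
  expect_equal(st$df, 1)

  ## F2 135:256:60 against 1:2:1
  st2 <- segregation_test(c(135, 256, 60), c(1, 2, 1), locus = "SNP3")
  expect_equal(st2$chi2, oracle_gof_chisq(c(135, 256, 60), c(1, 2, 1)))
  expect_equal(round(st2$chi2, 2), 33.2)
  expect_equal(st2$df, 2)

  ## exact expectation -> chi2 = 0, p = 1
  st0 <- segregation_test(c(25, 50, 25), c(1, 2, 1))
  expect_equal(c(st0$chi2, st0$p), c(0, 1))

  ## randomized oracle equivalence on integer tables
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    obs <- rpois(k, 40) + 1
    ratio <- sample(1:3, k, replace = TRUE)
    expect_equal(segregation_test(obs, ratio)$chi2, oracle_gof_chisq(obs, ratio))
  }

  expect_error(segregation_test(c(5), c(1)), "2 genotype classes")
  expect_error(segregation_test(c(0, 0), c(1, 1)), "zero")
  expect_error(segregation_test(c(3, 4), c(1, -1)), "positive")
})

test_that("Pearson correlation matches the closed form and is calibrated", {
  x <- 1:10
  expect_equal(pearson_correlation_test(x, 2 * x + 1)$r, 1)

  hx <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  hy <- c(2.0, 3.9, 2.5, 6.1, 3.8)
  r <- pearson_correlation_test(hx, hy)
  expect_equal(r$r, oracle_pearson_r(hx, hy))

  ## null calibration at the study's panel size (n = 39)
  set.seed(9)
  n_reps <- 2000
  rej <- vapply(seq_len(n_reps), function(i) {
    pearson_correlation_test(rnorm(39), rnorm(39))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_reps))

  expect_error(pearson_correlation_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation_test(1:2, 1:2), "3 complete pairs")
})

test_that("association table enumerates sites x timepoints x conditioning cells", {
  set.seed(10)
  ids <- sprintf("l%03d", 1:60)
  geno <- cbind(SNP3 = rep(c(0L, 2L), 30), IndelI = rep(c(0L, 0L, 2L, 2L), 15))
  rownames(geno) <- ids
  pheno <- expand.grid(line_id = ids, timepoint = c("40DAG", "50DAG"),
                       stringsAsFactors = FALSE)
  pheno$trait <- "tiller_number"
  pheno$value <- rnorm(nrow(pheno), 10)

  plan <- list(list(site = "SNP3"), list(site = "IndelI"))
  tab <- association_table(pheno, geno, plan)
  expect_equal(nrow(tab), 4L)   # 2 sites x 2 timepoints

  ## with conditioning cells the layout mirrors the conditional analysis
  plan2 <- list(list(site = "IndelI", condition_site = "SNP3",
                     condition_genotype = 2L, label = "IndelI|SNP3hom"),
                list(site = "SNP3", condition_site = "IndelI",
                     condition_genotype = 2L, label = "SNP3|IndelIhom"))
  tab2 <- association_table(pheno, geno, plan2)
  expect_equal(nrow(tab2), 4L)
  expect_setequal(unique(tab2$comparison), c("IndelI|SNP3hom", "SNP3|IndelIhom"))
  expect_true(all(tab2$n_conditioned == 30L))

  ## orphan identifiers are an error
  pheno_orphan <- rbind(pheno, data.frame(line_id = "ghost", timepoint = "40DAG",
                                          trait = "tiller_number", value = 5))
  expect_error(association_table(pheno_orphan, geno, plan), "ghost")
})

test_that("programmed effects are recovered through the full table", {
  geno <- matrix(c(rep(2L, 135), rep(0L, 60)), ncol = 1,
                 dimnames = list(sprintf("l%03d", 1:195), "SNP3"))
  pm <- phenotype_model(additive_effects = matrix(c(0.47, 2.77) / 2, nrow = 1))
  ph <- simulate_phenotypes(geno, pm, seed = 21)
  tab <- association_table(ph, geno, list(list(site = "SNP3")))
  eff50 <- tab$effect_size[tab$timepoint == "50DAG"]
  expect_lt(abs(eff50 - 2.77), 1.2)
  ## group SNP3_0 (dosage 0) has fewer tillers than SNP3_2
  expect_equal(tab$direction[tab$timepoint == "50DAG"], "SNP3_0 < SNP3_2")
})
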