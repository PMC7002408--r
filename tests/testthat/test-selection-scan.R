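# Nei FST, windowed scan, branch lengths, PBS, per-gene counts, HKA test and
# candidate calling.

test_that("site FST matches the GST hand evaluation and its symmetries", {
  expect_equal(site_fst(0.5, 0.5)$fst, 0)
  expect_equal(site_fst(1, 0)$fst, 1)
  r <- site_fst(0.2, 0.8)
  expect_equal(c(r$HT, r$HS, r$fst), c(0.5, 0.32, 0.36))

  ## monomorphic in both: defined 0, flagged non-segregating
  r0 <- site_fst(0, 0)
  expect_equal(r0$fst, 0)
  expect_false(r0$segregating)

  ## symmetry and allele-relabel invariance over random frequency pairs
  set.seed(1)
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(site_fst(p1, p2)$fst, site_fst(p2, p1)$fst)
  expect_equal(site_fst(p1, p2)$fst, site_fst(1 - p1, 1 - p2)$fst)
  expect_true(all(site_fst(p1, p2)$fst >= 0 & site_fst(p1, p2)$fst <= 1))

  expect_error(site_fst(1.2, 0.5), "\\[0, 1\\]")
})

test_that("windowed scan tiles the chromosome and conserves SNPs", {
  ## 3 SNPs in one window: unweighted mean
  w <- window_fst(data.frame(pos = c(100L, 200L, 300L), fst = c(0.1, 0.2, 0.3)),
                  chrom_length = 20000, window = 20000, step = 2000)
  expect_equal(w$mean_fst[1], 0.2)

  ## floor((L - w)/s) + 1 windows
  sites <- data.frame(pos = 10500L, fst = 0.5)
  w2 <- window_fst(sites, chrom_length = 1e5)
  expect_equal(nrow(w2), 41L)

  ## enumeration oracle: pos 10500 lies in windows with start <= 10500 <
  ## start + 20000, i.e. starts 0, 2000, ..., 10000
  containing <- w2[w2$n_snps > 0, ]
  expect_equal(containing$start, seq(0L, 10000L, 2000L))
  expect_equal(nrow(containing), 6L)

  ## conservation: every SNP appears in >= 1 window, in <= window/step windows
  set.seed(2)
  pos <- sort(sample.int(80000, 500))
  ws <- window_fst(data.frame(pos = pos, fst = runif(500)), chrom_length = 1e5)
  per_snp <- vapply(pos, function(p) sum(ws$start <= p & p < ws$end), integer(1))
  expect_true(all(per_snp >= 1))
  expect_true(all(per_snp <= 20000 / 2000))
  expect_equal(sum(ws$n_snps), sum(per_snp))

  expect_error(window_fst(sites, 1e5, window = 1000, step = 2000), "step")
})

test_that("top-quantile thresholding flags the upper tail with ties included", {
  tq <- top_quantile_threshold(1:1000, 0.005)
  expect_equal(which(tq$flagged), 996:1000)

  all_equal <- top_quantile_threshold(rep(3.5, 10), 0.1)
  expect_true(all(all_equal$flagged))

  two <- top_quantile_threshold(c(1, 2), 0.5)
  expect_equal(which(two$flagged), 2L)

  expect_error(top_quantile_threshold(c(NA_real_, NA_real_), 0.1), "no finite")
})

test_that("Cavalli-Sforza transform and PBS match closed forms", {
  expect_equal(branch_length_T(0), 0)
  expect_equal(branch_length_T(0.36), -log(0.64))
  expect_gt(branch_length_T(0.5), branch_length_T(0.4))
  expect_warning(t1 <- branch_length_T(1), "clamped")
  expect_true(is.finite(t1))
  expect_error(branch_length_T(-0.1), "\\[0, 1\\]")

  t <- 0.7
  expect_equal(as.numeric(pbs_score(t, t, t)), t / 2)
  expect_equal(as.numeric(pbs_score(0.44629, 0.44629, 0)), 0.44629)
  expect_equal(as.numeric(pbs_score(0, 0, 1)), -0.5)   # sign convention
  ## invariant under swapping populations 2 and 3 (standard mode)
  expect_equal(as.numeric(pbs_score(0.3, 0.5, 0.2)),
               as.numeric(pbs_score(0.5, 0.3, 0.2)))
  ## paper-literal mode sums all three branches and records the mode
  pl <- pbs_score(0.3, 0.5, 0.2, mode = "paper")
  expect_equal(as.numeric(pl), 0.5)
  expect_equal(attr(pl, "mode"), "paper")
  expect_error(pbs_score(-0.1, 0, 0), ">= 0")
})

test_that("per-gene A/B counts follow the fixed-against-both rule", {
  ## gene with 4 coding SNPs fixed in the target and absent elsewhere:
  ## B = 4 (FST = 1 > 0.9 vs both), A = 0 (not segregating in target)
  gm <- matrix_from_freqs(c(100L, 200L, 300L, 400L, 5000L),
                          list(target = c(1, 1, 1, 1, 0.5),
                               sister = c(0, 0, 0, 0, 0.5),
                               third = c(0, 0, 0, 0, 0.5)))
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr09",
                      start = c(50L, 4500L), end = c(450L, 5500L), strand = "+")
  gs <- gene_fst_and_counts(gm, genes, "target")
  expect_equal(gs$B[gs$gene_id == "gA"], 4L)
  expect_equal(gs$A[gs$gene_id == "gA"], 0L)
  expect_equal(gs$fst12[gs$gene_id == "gA"], 1)
  expect_equal(gs$A[gs$gene_id == "gB"], 1L)
  expect_equal(gs$B[gs$gene_id == "gB"], 0L)

  ## high FST against only one other population does not count in B
  gm2 <- matrix_from_freqs(100L, list(target = 1, sister = 0, third = 0.55),
                           n_diploids = 10)
  g2 <- data.frame(gene_id = "g", chrom = "chr09", start = 1L, end = 200L,
                   strand = "+")
  s2 <- gene_fst_and_counts(gm2, g2, "target")
  expect_equal(s2$B, 0L)

  ## gene with no coding SNPs: A = B = 0, missing FST, not an error
  g3 <- data.frame(gene_id = "empty", chrom = "chr09", start = 9000L,
                   end = 9500L, strand = "+")
  s3 <- gene_fst_and_counts(gm, g3, "target")
  expect_equal(c(s3$A, s3$B), c(0L, 0L))
  expect_true(is.na(s3$fst12))
})

test_that("gene statistics equal a brute-force per-site enumeration", {
  m <- population_model(n_sites = 2000, chrom_length_bp = 2e5,
                        n_diploids_per_pop = 15)
  gm <- simulate_three_pop_genotypes(m, seed = 31)
  genes <- tillersweep:::tiling_genes("chr09", 2e5, 40, gene_length = 3000)
  gs <- gene_fst_and_counts(gm, genes, "upland_jap")

  freq <- pop_allele_freqs(gm, c("upland_jap", "irrigated_jap", "indica"))
  gst <- function(p, q) {
    pb <- (p + q) / 2; HT <- 2 * pb * (1 - pb)
    HS <- p * (1 - p) + q * (1 - q)
    if (HT == 0) 0 else (HT - HS) / HT
  }
  for (i in sample(nrow(genes), 10)) {
    idx <- which(gm$pos >= genes$start[i] & gm$pos <= genes$end[i])
    if (length(idx) == 0) next
    A <- 0L; B <- 0L; f12 <- f13 <- f23 <- numeric(0)
    for (j in idx) {
      p1 <- freq[j, 1]; p2 <- freq[j, 2]; p3 <- freq[j, 3]
      if (p1 > 0 && p1 < 1) A <- A + 1L
      if (gst(p1, p2) > 0.9 && gst(p1, p3) > 0.9) B <- B + 1L
      f12 <- c(f12, gst(p1, p2)); f13 <- c(f13, gst(p1, p3)); f23 <- c(f23, gst(p2, p3))
    }
    row <- gs[gs$gene_id == genes$gene_id[i], ]
    expect_identical(row$A, A)
    expect_identical(row$B, B)
    expect_equal(row$fst12, mean(f12))
    expect_equal(row$pbs, (-log(1 - mean(f12)) - log(1 - mean(f13)) +
                             log(1 - mean(f23))) / 2)
  }
})

test_that("HKA chi-square equals the contingency-table oracle", {
  null_case <- hka_test(10, 5, 1000, 500)
  expect_equal(null_case$chi2, 0)
  expect_equal(null_case$p, 1)

  ht <- hka_test(10, 5, 1000, 50)   # table [[10,5],[990,45]]
  expect_equal(ht$chi2, oracle_chisq_2x2(10, 5, 990, 45))
  expect_equal(ht$p, pchisq(ht$chi2, 1, lower.tail = FALSE))

  ## homogeneity: doubling all cells doubles the statistic
  ht2 <- hka_test(20, 10, 2000, 100)
  expect_equal(ht2$chi2, 2 * ht$chi2)

  ## random small tables against the oracle
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:30, 1); b <- sample(1:30, 1)
    A <- a + sample(1:500, 1); B <- b + sample(1:500, 1)
    expect_equal(hka_test(a, b, A, B)$chi2,
                 oracle_chisq_2x2(a, b, A - a, B - b))
  }

  expect_error(hka_test(10, 0, 1000, 0), "zero margin")
  expect_error(hka_test(10, 5, 5, 100), "genome totals")
  expect_true(hka_test(1, 1, 1000, 2)$low_count)
})

test_that("candidate calling intersects PBS tail with HKA significance", {
  gs <- data.frame(gene_id = paste0("g", 1:10), n_coding_snps = 5L,
                   fst12 = 0.2, fst13 = 0.2, fst23 = 0.2,
                   T12 = 0.22, T13 = 0.22, T23 = 0.22, pbs = 0.11,
                   A = 5L, B = 1L, chi2 = 5, hka_p = 0.01, hka_low_count = FALSE)
  ## exchangeable genes: all flagged or none, never a strict subset
  cand <- sweep_candidates(gs, scan_thresholds())
  expect_true(nrow(cand) %in% c(0L, nrow(gs)))
  expect_equal(nrow(cand), nrow(gs))   # ties at the quantile all included

  gs_ns <- gs; gs_ns$hka_p <- 0.5
  expect_equal(nrow(sweep_candidates(gs_ns, scan_thresholds())), 0L)

  ## an impossibly small alpha empties the list
  cand0 <- sweep_candidates(gs, scan_thresholds(hka_alpha = 1e-15))
  expect_equal(nrow(cand0), 0L)

  ## output sorted by PBS descending
  gs_var <- gs; gs_var$pbs <- seq(0.1, 1, length.out = 10)
  cand_v <- sweep_candidates(gs_var, scan_thresholds(pbs_quantile = 0.3))
  expect_false(is.unsorted(rev(cand_v$pbs)))
})
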