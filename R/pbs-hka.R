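## Population branch statistic and the polymorphism/fixation (HKA-style)
## chi-square test, computed per gene over coding SNPs.

#' Cavalli-Sforza branch-length transform
#'
#' `T = -log(1 - FST)` (natural logarithm), the classical transform of
#' pairwise FST into a divergence time scaled by population size. `FST = 1`
#' is clamped to `1 - 1e-12` with a warning.
#'
#' @param fst FST value(s) in `[0, 1]`.
#' @return Branch length(s) `T >= 0`.
#' @export
branch_length_T <- function(fst) {
  check_prob(fst, "fst")
  if (any(fst == 1)) {
    warning("FST of 1 clamped to 1 - 1e-12 in branch-length transform")
    fst[fst == 1] <- 1 - 1e-12
  }
  -log(1 - fst)
}

#' Population branch statistic
#'
#' Branch length of population 1 on the three-population tree. The default
#' `"standard"` mode computes `(T12 + T13 - T23)/2` (the usual PBS; may be
#' negative). A `"paper"` mode computes `(T12 + T13 + T23)/2`, the literal
#' printed form of the source equation, almost certainly a typesetting slip
#' -- it is provided so the user can decide. The mode used is recorded in the
#' `"mode"` attribute of the result.
#'
#' @param T12,T13,T23 Non-negative branch-scaled divergences from
#'   [branch_length_T()]; `T12` and `T13` involve the focal population.
#' @param mode `"standard"` (default) or `"paper"`.
#' @return PBS value(s) with attribute `mode`.
#' @export
pbs_score <- function(T12, T13, T23, mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  if (any(c(T12, T13, T23) < 0, na.rm = TRUE)) stop_invalid("branch lengths must be >= 0")
  out <- if (mode == "standard") (T12 + T13 - T23) / 2 else (T12 + T13 + T23) / 2
  attr(out, "mode") <- mode
  out
}

#' Scan thresholds
#'
#' @param window_quantile Upper tail for the windowed FST call (default
#'   0.005, the genome-wide top 5 per-mille).
#' @param pbs_quantile Upper tail for the PBS call (default 0.05, top 5%).
#' @param hka_alpha Nominal significance level of the HKA-style test.
#' @param fixation_fst_cutoff FST above which a site counts as fixed between
#'   two populations (strict inequality; default 0.9).
#' @return A `scan_thresholds` list.
#' @export
scan_thresholds <- function(window_quantile = 0.005, pbs_quantile = 0.05,
                            hka_alpha = 0.05, fixation_fst_cutoff = 0.9) {
  for (v in c(window_quantile, pbs_quantile, hka_alpha, fixation_fst_cutoff)) {
    if (v <= 0 || v >= 1) stop_invalid("all thresholds must lie in (0, 1)")
  }
  structure(list(window_quantile = window_quantile, pbs_quantile = pbs_quantile,
                 hka_alpha = hka_alpha, fixation_fst_cutoff = fixation_fst_cutoff),
            class = "scan_thresholds")
}

#' Per-gene FST, branch lengths, PBS and polymorphism/fixation counts
#'
#' For each gene, using SNPs located in its (merged) coding intervals:
#' pairwise mean Nei FST between the three populations, Cavalli-Sforza branch
#' lengths, the PBS of the target population, the count `A` of sites
#' segregating within the target population, and the count `B` of sites with
#' pairwise FST above `fixation_fst_cutoff` against *both* other populations.
#' A gene with no coding SNPs is reported with `A = B = 0` and missing FST.
#'
#' @param gm A [genotype_matrix()].
#' @param genes Gene annotation data frame from [read_genes()] (columns
#'   `gene_id`, `chrom`, `start`, `end`; multiple rows per gene allowed).
#' @param target_pop Focal population (population 1 of the PBS).
#' @param fixation_fst_cutoff See [scan_thresholds()].
#' @param pbs_mode Passed to [pbs_score()].
#' @param a_definition `"focal"` (default): `A` counts sites segregating in
#'   the target population; `"any_pop"`: sites segregating in at least one of
#'   the three populations. The source text is ambiguous; both readings are
#'   provided.
#' @return Data frame with one row per gene: `gene_id`, `n_coding_snps`,
#'   `fst12`, `fst13`, `fst23`, `T12`, `T13`, `T23`, `pbs`, `A`, `B`.
#' @export
gene_fst_and_counts <- function(gm, genes, target_pop,
                                fixation_fst_cutoff = 0.9,
                                pbs_mode = "standard",
                                a_definition = c("focal", "any_pop")) {
  a_definition <- match.arg(a_definition)
  pops <- populations(gm)
  if (!target_pop %in% pops) stop_invalid("unknown target population '%s'", target_pop)
  if (length(pops) != 3L) stop_invalid("three populations are required")
  others <- setdiff(pops, target_pop)
  freq <- pop_allele_freqs(gm, c(target_pop, others))
  p1 <- freq[, 1]; p2 <- freq[, 2]; p3 <- freq[, 3]
  fst12_site <- fst_nei(p1, p2)
  fst13_site <- fst_nei(p1, p3)
  fst23_site <- fst_nei(p2, p3)
  seg <- if (a_definition == "focal") {
    p1 > 0 & p1 < 1
  } else {
    (p1 > 0 & p1 < 1) | (p2 > 0 & p2 < 1) | (p3 > 0 & p3 < 1)
  }
  fixed_both <- fst12_site > fixation_fst_cutoff & fst13_site > fixation_fst_cutoff

  ids <- unique(genes$gene_id)
  res <- lapply(ids, function(id) {
    iv <- genes[genes$gene_id == id & genes$chrom == gm$chrom, , drop = FALSE]
    idx <- integer(0)
    for (r in seq_len(nrow(iv))) {
      idx <- c(idx, which(gm$pos >= iv$start[r] & gm$pos <= iv$end[r]))
    }
    idx <- unique(idx)
    if (length(idx) == 0) {
      return(data.frame(gene_id = id, n_coding_snps = 0L,
                        fst12 = NA_real_, fst13 = NA_real_, fst23 = NA_real_,
                        A = 0L, B = 0L))
    }
    data.frame(gene_id = id, n_coding_snps = length(idx),
               fst12 = mean(fst12_site[idx]),
               fst13 = mean(fst13_site[idx]),
               fst23 = mean(fst23_site[idx]),
               A = sum(seg[idx]), B = sum(fixed_both[idx]))
  })
  out <- do.call(rbind, res)
  ## branch transform with NA pass-through; FST of 1 clamped as in branch_length_T
  tr <- function(f) ifelse(is.na(f), NA_real_, -log(1 - pmin(f, 1 - 1e-12)))
  out$T12 <- tr(out$fst12); out$T13 <- tr(out$fst13); out$T23 <- tr(out$fst23)
  out$pbs <- as.numeric(pbs_score(ifelse(is.na(out$T12), 0, out$T12),
                                  ifelse(is.na(out$T13), 0, out$T13),
                                  ifelse(is.na(out$T23), 0, out$T23),
                                  mode = pbs_mode))
  out$pbs[is.na(out$fst12)] <- NA_real_
  attr(out, "pbs_mode") <- pbs_mode
  out[, c("gene_id", "n_coding_snps", "fst12", "fst13", "fst23",
          "T12", "T13", "T23", "pbs", "A", "B")]
}

#' HKA-style polymorphism/fixation chi-square test
#'
#' Tests the null that a gene's ratio of segregating (`A`) to fixed (`B`)
#' sites equals the genome-wide ratio, via Pearson's chi-square (no
#' continuity correction, 1 df) on the 2x2 table
#' `[[A_gene, B_gene], [A_genome - A_gene, B_genome - B_gene]]`. A deficit of
#' polymorphism relative to fixation suggests a sweep. Any expected cell
#' below 1 flags the result `low_count`.
#'
#' @param A_gene,B_gene Gene counts.
#' @param A_genome,B_genome Genome-wide totals (must be at least the gene
#'   counts; a zero table margin is an undefined test and an error).
#' @return List with `chi2`, `p`, `table`, `low_count`.
#' @export
hka_test <- function(A_gene, B_gene, A_genome, B_genome) {
  if (A_genome < A_gene || B_genome < B_gene) {
    stop_invalid("genome totals must be >= gene counts")
  }
  tbl <- rbind(gene = c(A = A_gene, B = B_gene),
               rest = c(A = A_genome - A_gene, B = B_genome - B_gene))
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    stop_invalid("zero margin in the HKA table: test undefined")
  }
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  ht <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value), table = tbl,
       low_count = any(expected < 1))
}

#' Per-gene HKA tests against genome-wide totals
#'
#' Runs [hka_test()] for every gene in a [gene_fst_and_counts()] table, with
#' genome totals taken as the column sums of `A` and `B` over all genes.
#' Genes whose 2x2 table has a zero margin after removal (never, given
#' positive totals) or with no coding SNPs get missing results.
#'
#' @param gene_stats Output of [gene_fst_and_counts()].
#' @return `gene_stats` with added columns `chi2`, `hka_p`, `hka_low_count`.
#' @export
hka_scan <- function(gene_stats) {
  A_tot <- sum(gene_stats$A)
  B_tot <- sum(gene_stats$B)
  n <- nrow(gene_stats)
  chi2 <- p <- rep(NA_real_, n)
  low <- rep(NA, n)
  if (A_tot == 0 || B_tot == 0) {
    warning("zero genome-wide margin: HKA tests undefined for all genes")
  } else {
    for (i in seq_len(n)) {
      if (gene_stats$n_coding_snps[i] == 0) next
      ## a gene with A = B = 0 (or one holding an entire margin) has an
      ## undefined 2x2 test; reported as missing rather than an error
      if (gene_stats$A[i] + gene_stats$B[i] == 0) next
      if ((A_tot - gene_stats$A[i]) + (B_tot - gene_stats$B[i]) == 0) next
      ht <- hka_test(gene_stats$A[i], gene_stats$B[i], A_tot, B_tot)
      chi2[i] <- ht$chi2; p[i] <- ht$p; low[i] <- ht$low_count
    }
  }
  gene_stats$chi2 <- chi2
  gene_stats$hka_p <- p
  gene_stats$hka_low_count <- low
  gene_stats
}

#' Call sweep-candidate genes
#'
#' Candidates are the intersection of the genes with PBS at or above the
#' empirical `(1 - pbs_quantile)` quantile and an HKA P-value below
#' `hka_alpha`, sorted by PBS descending.
#'
#' @param gene_stats Output of [hka_scan()].
#' @param thresholds A [scan_thresholds()].
#' @return `gene_stats` rows of the candidates, with a `candidate` column
#'   added to the full table in the `"gene_stats"` attribute.
#' @export
sweep_candidates <- function(gene_stats, thresholds = scan_thresholds()) {
  stopifnot(inherits(thresholds, "scan_thresholds"))
  if (!"hka_p" %in% names(gene_stats)) gene_stats <- hka_scan(gene_stats)
  tq <- top_quantile_threshold(gene_stats$pbs, thresholds$pbs_quantile)
  gene_stats$candidate <- tq$flagged &
    !is.na(gene_stats$hka_p) & gene_stats$hka_p < thresholds$hka_alpha
  cand <- gene_stats[gene_stats$candidate, , drop = FALSE]
  cand <- cand[order(-cand$pbs), , drop = FALSE]
  attr(cand, "gene_stats") <- gene_stats
  attr(cand, "pbs_threshold") <- tq$threshold
  cand
}
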