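## Genotype-phenotype layer: homozygote-group Student's t-tests, conditional
## association, segregation-distortion chi-squares and expression-phenotype
## Pearson correlation -- the statistics behind the association tables of a
## candidate-gene study.

#' Split accessions into the two homozygote groups of a biallelic site
#'
#' Heterozygotes and missing calls are excluded (counts reported). A site
#' whose minor homozygote class makes up less than `rare_cutoff` of the
#' homozygotes is flagged `rare` and should not be tested; a site with fewer
#' than 2 accessions in either group is flagged `untestable`.
#'
#' @param genotypes Integer vector of dosage codes (0, 1, 2, `NA`) named by
#'   accession, or unnamed.
#' @param rare_cutoff Minor-homozygote frequency below which the site is
#'   flagged rare (default 0.05).
#' @return List with `group0`, `group2` (indices or names), `n_het`,
#'   `n_missing`, `rare`, `untestable`.
#' @export
homozygote_groups <- function(genotypes, rare_cutoff = 0.05) {
  ids <- names(genotypes) %||% seq_along(genotypes)
  g0 <- ids[!is.na(genotypes) & genotypes == 0]
  g2 <- ids[!is.na(genotypes) & genotypes == 2]
  n_het <- sum(!is.na(genotypes) & genotypes == 1)
  n_missing <- sum(is.na(genotypes))
  n_hom <- length(g0) + length(g2)
  rare <- n_hom > 0 && min(length(g0), length(g2)) / n_hom < rare_cutoff
  untestable <- length(g0) < 2 || length(g2) < 2
  list(group0 = g0, group2 = g2, n_het = n_het, n_missing = n_missing,
       rare = rare, untestable = untestable)
}

#' Two-group Student's t-test with association summaries
#'
#' Pooled-variance two-sample Student's t-test (two-sided), plus the
#' summaries reported in candidate-gene association tables: `effect_size` is
#' the absolute difference of group means in trait units (tillers);
#' `mean_value_difference` is the percent difference relative to the
#' lower-mean group; `pooled_variance` is the pooled within-group variance.
#' With zero pooled variance, equal means give `t = 0, p = 1`; unequal means
#' give a p-value at the machine floor with a `degenerate` flag.
#'
#' @param x1,x2 Numeric phenotype vectors for the two groups (`n >= 2` each).
#' @param labels Length-2 character vector naming the groups.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student form (default `FALSE`; the pooled form is the study's test).
#' @return One-row data frame: group labels and sizes, means, `t`, `df`, `p`,
#'   `effect_size`, `mean_value_difference`, `pooled_variance`, `direction`,
#'   `degenerate`.
#' @export
t_test_association <- function(x1, x2, labels = c("group1", "group2"),
                               welch = FALSE) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop_invalid("each group needs at least 2 observations")
  m1 <- mean(x1); m2 <- mean(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  dfree <- n1 + n2 - 2
  degenerate <- FALSE
  if (sp2 == 0) {
    if (m1 == m2) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(m1 - m2) * Inf; p <- .Machine$double.xmin; degenerate <- TRUE
    }
  } else {
    ht <- stats::t.test(x1, x2, var.equal = !welch)
    tstat <- unname(ht$statistic); p <- ht$p.value; dfree <- unname(ht$parameter)
  }
  m_low <- min(m1, m2); m_high <- max(m1, m2)
  mvd <- if (m_low == 0) NA_real_ else 100 * (m_high - m_low) / m_low
  direction <- if (m1 == m2) {
    sprintf("%s == %s", labels[1], labels[2])
  } else if (m1 > m2) {
    sprintf("%s > %s", labels[1], labels[2])
  } else {
    sprintf("%s < %s", labels[1], labels[2])
  }
  data.frame(group1 = labels[1], group2 = labels[2], n1 = n1, n2 = n2,
             mean1 = m1, mean2 = m2, t = tstat, df = dfree, p = p,
             effect_size = abs(m1 - m2), mean_value_difference = mvd,
             pooled_variance = sp2, direction = direction,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Conditional association of one site given a genotype at another
#'
#' Subsets to the accessions homozygous for `required_genotype_B` at the
#' conditioning site, then tests site A's homozygote groups with
#' [t_test_association()]. Used to disentangle two linked candidate variants.
#'
#' @param geno_A,geno_B Named dosage vectors at the tested and conditioning
#'   sites (shared accession names).
#' @param required_genotype_B Dosage class (0 or 2) to condition on.
#' @param phenotypes Named numeric vector of trait values by accession.
#' @param labels Group labels for site A's homozygote classes (0 first).
#' @param rare_cutoff Passed to [homozygote_groups()].
#' @return As [t_test_association()], with `n_conditioned` added, or a
#'   one-row data frame with `untestable = TRUE` if the subset leaves fewer
#'   than 2 accessions in either group (or the conditioning class is empty).
#' @export
conditional_association <- function(geno_A, geno_B, required_genotype_B,
                                    phenotypes, labels = c("A0", "A2"),
                                    rare_cutoff = 0) {
  ids <- intersect(names(geno_A), intersect(names(geno_B), names(phenotypes)))
  keep <- ids[!is.na(geno_B[ids]) & geno_B[ids] == required_genotype_B]
  untestable_row <- data.frame(group1 = labels[1], group2 = labels[2],
                               n1 = NA_integer_, n2 = NA_integer_,
                               mean1 = NA_real_, mean2 = NA_real_, t = NA_real_,
                               df = NA_integer_, p = NA_real_,
                               effect_size = NA_real_,
                               mean_value_difference = NA_real_,
                               pooled_variance = NA_real_, direction = NA_character_,
                               degenerate = NA, n_conditioned = length(keep),
                               untestable = TRUE, stringsAsFactors = FALSE)
  if (length(keep) == 0) return(untestable_row)
  hg <- homozygote_groups(geno_A[keep], rare_cutoff = rare_cutoff)
  if (hg$untestable) return(untestable_row)
  res <- t_test_association(phenotypes[hg$group0], phenotypes[hg$group2],
                            labels = labels)
  res$n_conditioned <- length(keep)
  res$untestable <- FALSE
  res
}

#' Segregation-distortion goodness-of-fit test
#'
#' Pearson chi-square of observed genotype-class counts against an expected
#' ratio (e.g. 1:1 homozygotes in an F8 RIL, 1:2:1 in an F2), df =
#' classes - 1, no continuity correction.
#'
#' @param observed Non-negative integer counts per class.
#' @param expected_ratio Positive expected ratio (same length).
#' @param locus Optional locus name for the output.
#' @return List `locus`, `observed`, `expected`, `chi2`, `df`, `p`.
#' @export
segregation_test <- function(observed, expected_ratio, locus = NA_character_) {
  if (length(observed) < 2) stop_invalid("at least 2 genotype classes required")
  if (length(expected_ratio) != length(observed) || any(expected_ratio <= 0)) {
    stop_invalid("expected_ratio must be positive and match the class count")
  }
  if (sum(observed) == 0) stop_invalid("total observed count is zero")
  ht <- suppressWarnings(stats::chisq.test(observed, p = expected_ratio / sum(expected_ratio)))
  list(locus = locus, observed = observed,
       expected = sum(observed) * expected_ratio / sum(expected_ratio),
       chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation test
#'
#' Pearson product-moment correlation with the two-sided t-distributed test
#' of `r * sqrt((n - 2) / (1 - r^2))`. Used for expression-phenotype
#' correlations (e.g. transcript level vs tiller number). Zero variance in
#' either vector is undefined and an error.
#'
#' @param x,y Paired numeric vectors, `n >= 3`; pairs with a missing value
#'   are dropped.
#' @return List `r`, `p`, `n`.
#' @export
pearson_correlation_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_invalid("at least 3 complete pairs required")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_invalid("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Full association table over sites, timepoints and conditioning cells
#'
#' Builds the candidate-gene association table: one row per (comparison,
#' timepoint), where each comparison tests a site's homozygote groups,
#' optionally conditioning on a homozygous class at a second site. Phenotype
#' and genotype data are joined on accession identifiers; orphan identifiers
#' on either side are an error.
#'
#' @param phenotypes Long data frame from [read_phenotypes()] or
#'   [simulate_phenotypes()] (`line_id`, `timepoint`, `trait`, `value`).
#' @param genotypes Integer matrix, accessions x sites, of dosage codes with
#'   row and column names, or a [genotype_matrix()] (transposed internally;
#'   site columns named by position when unnamed).
#' @param plan List of comparisons; each a list with `site`, optional
#'   `condition_site` and `condition_genotype` (0 or 2), optional `labels`
#'   (length-2 names for the site's 0- and 2-dosage homozygote groups) and
#'   optional `label` for the comparison.
#' @param timepoints Timepoints to analyze (default: all present).
#' @param rare_cutoff Passed to [homozygote_groups()] for unconditioned
#'   comparisons.
#' @return Data frame: one [t_test_association()] row per comparison and
#'   timepoint, with `comparison`, `site`, `timepoint` and flag columns.
#' @export
association_table <- function(phenotypes, genotypes, plan,
                              timepoints = unique(phenotypes$timepoint),
                              rare_cutoff = 0.05) {
  if (inherits(genotypes, "genotype_matrix")) {
    g <- t(genotypes$geno)
    colnames(g) <- colnames(g) %||% as.character(genotypes$pos)
    genotypes <- g
  }
  if (is.null(rownames(genotypes))) stop_invalid("genotype rows must be named by accession")
  orphans <- setdiff(unique(phenotypes$line_id), rownames(genotypes))
  if (length(orphans)) {
    stop_invalid("phenotyped accession(s) without genotypes: %s",
                 paste(utils::head(orphans, 5), collapse = ", "))
  }
  rows <- list()
  for (cmp in plan) {
    site <- cmp$site
    if (!site %in% colnames(genotypes)) stop_invalid("unknown site '%s'", site)
    labels <- cmp$labels %||% paste0(site, c("_0", "_2"))
    for (tp in timepoints) {
      ph <- phenotypes[phenotypes$timepoint == tp, , drop = FALSE]
      phv <- stats::setNames(ph$value, ph$line_id)
      gA <- stats::setNames(genotypes[, site], rownames(genotypes))
      gA <- gA[names(gA) %in% names(phv)]
      if (!is.null(cmp$condition_site)) {
        gB <- stats::setNames(genotypes[, cmp$condition_site], rownames(genotypes))
        res <- conditional_association(gA, gB, cmp$condition_genotype, phv,
                                       labels = labels)
        res$rare <- FALSE
      } else {
        hg <- homozygote_groups(gA, rare_cutoff = rare_cutoff)
        if (hg$untestable || hg$rare) {
          res <- data.frame(group1 = labels[1], group2 = labels[2],
                            n1 = length(hg$group0), n2 = length(hg$group2),
                            mean1 = NA_real_, mean2 = NA_real_, t = NA_real_,
                            df = NA_integer_, p = NA_real_, effect_size = NA_real_,
                            mean_value_difference = NA_real_,
                            pooled_variance = NA_real_, direction = NA_character_,
                            degenerate = NA, n_conditioned = NA_integer_,
                            untestable = hg$untestable, stringsAsFactors = FALSE)
          res$rare <- hg$rare
        } else {
          res <- t_test_association(phv[hg$group0], phv[hg$group2], labels = labels)
          res$n_conditioned <- NA_integer_
          res$untestable <- FALSE
          res$rare <- FALSE
        }
      }
      res <- cbind(data.frame(comparison = cmp$label %||% site, site = site,
                              timepoint = tp, stringsAsFactors = FALSE), res)
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
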