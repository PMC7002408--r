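#' Additive tiller-number phenotype model
#'
#' Tiller counts are generated per plant as baseline + sum of additive locus
#' effects + Gaussian noise, then averaged over the plants of a line (field
#' practice: ~8 plants scored per line). Effects are in tillers per copy of
#' the derived/B allele, so the homozygote contrast is twice the per-copy
#' effect. Defaults reflect rice tillering at the two scored timepoints:
#' ~10 tillers at 40 days after germination (DAG) and ~20 at 50 DAG, with
#' plant-level residual SD of 3.0 and 6.5 tillers respectively.
#'
#' @param timepoints Character vector of timepoint labels.
#' @param baseline_mu Baseline mean tiller number per timepoint.
#' @param additive_effects Matrix (loci x timepoints) of per-copy effects in
#'   tillers, or a vector for a single locus.
#' @param residual_sd Plant-level residual SD per timepoint, tillers.
#' @param plants_per_line Plants phenotyped and averaged per line.
#' @param seed Integer seed.
#' @return A `phenotype_model` list.
#' @export
phenotype_model <- function(timepoints = c("40DAG", "50DAG"),
                            baseline_mu = c(10, 20),
                            additive_effects = matrix(c(0.235, 1.385), nrow = 1,
                                                      dimnames = list("SNP3", NULL)),
                            residual_sd = c(3.0, 6.5),
                            plants_per_line = 8L,
                            seed = 1L) {
  nt <- length(timepoints)
  baseline_mu <- rep_len(baseline_mu, nt)
  residual_sd <- rep_len(residual_sd, nt)
  if (any(residual_sd <= 0)) stop_invalid("residual_sd must be > 0")
  plants_per_line <- check_positive_int(plants_per_line, "plants_per_line")
  if (is.vector(additive_effects)) {
    additive_effects <- matrix(additive_effects, nrow = 1)
  }
  if (ncol(additive_effects) != nt) {
    stop_invalid("additive_effects needs one column per timepoint")
  }
  structure(list(timepoints = timepoints, baseline_mu = baseline_mu,
                 additive_effects = additive_effects, residual_sd = residual_sd,
                 plants_per_line = plants_per_line, seed = as.integer(seed)),
            class = "phenotype_model")
}

#' Simulate line-level tiller phenotypes from causal genotypes
#'
#' @param genotypes Integer matrix, lines x causal loci, of allele-dosage
#'   codes (0, 1, 2), or a [genotype_matrix()] whose sites are the causal
#'   loci (it is transposed internally). Lines with a missing causal genotype
#'   are skipped with a warning.
#' @param model A [phenotype_model()].
#' @param seed Integer seed; defaults to `model$seed`.
#' @return Long-format data frame: `line_id`, `timepoint`, `trait`, `value`
#'   (line mean over `plants_per_line` plants).
#' @export
simulate_phenotypes <- function(genotypes, model, seed = model$seed) {
  stopifnot(inherits(model, "phenotype_model"))
  if (inherits(genotypes, "genotype_matrix")) {
    genotypes <- t(genotypes$geno)
  }
  genotypes <- as.matrix(genotypes)
  if (nrow(model$additive_effects) != ncol(genotypes)) {
    stop_invalid("additive_effects must have one row per causal locus")
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("line_%03d", seq_len(nrow(genotypes)))
  }
  miss <- rowSums(is.na(genotypes)) > 0
  if (any(miss)) {
    warning(sprintf("%d line(s) skipped: missing causal genotype", sum(miss)))
    genotypes <- genotypes[!miss, , drop = FALSE]
  }
  set.seed(seed)
  n <- nrow(genotypes)
  out <- vector("list", length(model$timepoints))
  for (t in seq_along(model$timepoints)) {
    mu <- model$baseline_mu[t] + drop(genotypes %*% model$additive_effects[, t])
    noise <- matrix(stats::rnorm(n * model$plants_per_line, 0, model$residual_sd[t]),
                    n, model$plants_per_line)
    out[[t]] <- data.frame(line_id = rownames(genotypes),
                           timepoint = model$timepoints[t],
                           trait = "tiller_number",
                           value = mu + rowMeans(noise),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
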