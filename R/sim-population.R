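## Synthetic three-population genotype data.
##
## The generative model is deliberately simple and analytically checkable:
## ancestral derived-allele frequencies follow the standard neutral 1/i law,
## population frequencies diverge from the ancestor under the Balding-Nichols
## Beta model (one drift parameter F per population), and genotypes are drawn
## binomially per diploid. An optional phenomenological sweep replaces the
## target population's derived frequency near a focal site by a high-frequency
## draw, with exponentially decaying probability in distance -- the minimal
## model that produces a U-shaped derived AFS decaying away from the focal
## mutation, as hitch-hiking does.

#' Three-population simulation model
#'
#' @param pop_labels Ordered triple of population names: target (the
#'   putatively selected population, e.g. upland japonica), sister (e.g.
#'   irrigated japonica), third/outgroup (e.g. indica).
#' @param n_diploids_per_pop Diploid sample size per population (length 3 or
#'   recycled scalar).
#' @param drift_F_per_pop Balding-Nichols drift parameter per population, each
#'   in (0, 1). Larger F means more drift from the shared ancestor. Rice
#'   subpopulations are strongly differentiated (selfing); defaults reflect
#'   moderate drift within japonica and strong drift to indica.
#' @param chrom_length_bp Chromosome length in bp.
#' @param n_sites Number of SNPs to place (uniformly, without replacement).
#' @param seed Integer seed; the simulation is a pure function of
#'   (parameters, seed).
#' @return A `population_model` list.
#' @export
population_model <- function(pop_labels = c("upland_jap", "irrigated_jap", "indica"),
                             n_diploids_per_pop = c(40, 40, 40),
                             drift_F_per_pop = c(0.2, 0.2, 0.5),
                             chrom_length_bp = 5e6,
                             n_sites = 5e4,
                             seed = 1L) {
  if (length(pop_labels) != 3L || anyDuplicated(pop_labels)) {
    stop_invalid("exactly three distinct population labels are required")
  }
  n_diploids_per_pop <- rep_len(check_positive_int(n_diploids_per_pop, "n_diploids_per_pop"), 3L)
  drift_F_per_pop <- rep_len(drift_F_per_pop, 3L)
  check_prob(drift_F_per_pop, "drift_F_per_pop", open = TRUE)
  chrom_length_bp <- check_positive_int(chrom_length_bp, "chrom_length_bp")
  n_sites <- check_positive_int(n_sites, "n_sites")
  if (n_sites > chrom_length_bp) stop_invalid("n_sites must not exceed chrom_length_bp")
  structure(list(pop_labels = pop_labels,
                 n_diploids_per_pop = n_diploids_per_pop,
                 drift_F_per_pop = drift_F_per_pop,
                 chrom_length_bp = chrom_length_bp,
                 n_sites = n_sites,
                 seed = as.integer(seed)),
            class = "population_model")
}

#' Sweep configuration for the synthetic generator
#'
#' Phenomenological hitch-hiking stand-in: at distance `d` from the focal
#' position, with probability `intensity_w0 * exp(-d / decay_length_bp)` the
#' target population's derived frequency is replaced by a uniform draw on
#' `[high_freq_floor, 1]`. `intensity_w0 = 0` reduces exactly to neutrality.
#'
#' @param focal_position_bp Position of the selected mutation (1-based).
#' @param target_pop Population experiencing the sweep.
#' @param intensity_w0 Mixture weight at distance zero, in `[0, 1]`.
#' @param decay_length_bp Exponential decay length of the sweep effect, bp.
#' @param high_freq_floor Lower bound of the swept derived frequency, in
#'   (0.5, 1).
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(focal_position_bp, target_pop = "upland_jap",
                         intensity_w0 = 0.9, decay_length_bp = 25000,
                         high_freq_floor = 0.95) {
  check_prob(intensity_w0, "intensity_w0")
  if (high_freq_floor <= 0.5 || high_freq_floor >= 1) {
    stop_invalid("high_freq_floor must lie in (0.5, 1)")
  }
  if (decay_length_bp <= 0) stop_invalid("decay_length_bp must be positive")
  structure(list(focal_position_bp = as.integer(focal_position_bp),
                 target_pop = target_pop,
                 intensity_w0 = intensity_w0,
                 decay_length_bp = decay_length_bp,
                 high_freq_floor = high_freq_floor),
            class = "sweep_config")
}

#' Neutral ancestral derived-allele frequencies
#'
#' Draws site frequencies from the standard neutral spectrum: the derived
#' count i in a sample of `sample_chroms` chromosomes is drawn with
#' probability proportional to 1/i, i in 1..(sample_chroms - 1), and the
#' frequency is i / sample_chroms.
#'
#' @param n_sites Number of sites.
#' @param sample_chroms Number of chromosomes in the (conceptual) ancestral
#'   sample; must be >= 2.
#' @param seed Optional integer seed (set for reproducibility).
#' @return Numeric vector of frequencies in (0, 1).
#' @export
draw_neutral_sfs_frequencies <- function(n_sites, sample_chroms, seed = NULL) {
  n_sites <- check_positive_int(n_sites, "n_sites")
  if (!is.numeric(sample_chroms) || sample_chroms < 2) {
    stop_invalid("sample_chroms must be >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(sample_chroms - 1)
  counts <- sample(i, n_sites, replace = TRUE, prob = 1 / i)
  counts / sample_chroms
}

#' Simulate genotypes for three diverged populations
#'
#' See [population_model()] and [sweep_config()] for the generative model.
#' Which of REF/ALT is the derived allele is randomized per site, and the true
#' ancestral allele is recorded in the matrix's `anc` field (optionally
#' corrupted at rate `polarization_error`). The returned object carries a
#' `"truth"` attribute with the ancestral and per-population frequencies and
#' the per-site sweep indicator, for recovery tests.
#'
#' @param model A [population_model()].
#' @param sweep A [sweep_config()] or `NULL` for neutrality.
#' @param seed Integer seed; defaults to `model$seed`.
#' @param polarization_error Probability that the recorded ancestral state is
#'   flipped (default 0: the simulator emits truth).
#' @return A [genotype_matrix()].
#' @export
simulate_three_pop_genotypes <- function(model, sweep = NULL, seed = model$seed,
                                         polarization_error = 0) {
  stopifnot(inherits(model, "population_model"))
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_config"))
    if (!sweep$target_pop %in% model$pop_labels) {
      stop_invalid("sweep target population '%s' is not in the model", sweep$target_pop)
    }
    if (sweep$focal_position_bp < 1 || sweep$focal_position_bp > model$chrom_length_bp) {
      stop_invalid("sweep focal position %d is off-chromosome", sweep$focal_position_bp)
    }
  }
  check_prob(polarization_error, "polarization_error")
  set.seed(seed)
  n <- model$n_sites
  pos <- sort(sample.int(model$chrom_length_bp, n))
  total_chroms <- 2L * sum(model$n_diploids_per_pop)
  p_anc <- draw_neutral_sfs_frequencies(n, total_chroms)

  ## Balding-Nichols: pop frequency ~ Beta with mean p and shape (1-F)/F
  pop_freq <- matrix(NA_real_, n, 3L, dimnames = list(NULL, model$pop_labels))
  for (k in 1:3) {
    shape <- (1 - model$drift_F_per_pop[k]) / model$drift_F_per_pop[k]
    pop_freq[, k] <- stats::rbeta(n, p_anc * shape, (1 - p_anc) * shape)
  }

  swept <- logical(n)
  if (!is.null(sweep) && sweep$intensity_w0 > 0) {
    d <- abs(pos - sweep$focal_position_bp)
    swept <- stats::runif(n) < sweep$intensity_w0 * exp(-d / sweep$decay_length_bp)
    k <- match(sweep$target_pop, model$pop_labels)
    pop_freq[swept, k] <- stats::runif(sum(swept), sweep$high_freq_floor, 1)
  }

  ## Randomize which allele is derived; calls count ALT copies.
  derived_is_alt <- stats::runif(n) < 0.5
  alt_freq <- pop_freq
  alt_freq[!derived_is_alt, ] <- 1 - alt_freq[!derived_is_alt, , drop = FALSE]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  geno <- matrix(NA_integer_, n, sum(model$n_diploids_per_pop))
  sample_pop <- character(ncol(geno))
  col0 <- 0L
  for (k in 1:3) {
    nd <- model$n_diploids_per_pop[k]
    cols <- col0 + seq_len(nd)
    geno[, cols] <- stats::rbinom(n * nd, 2L, rep(alt_freq[, k], nd))
    sample_pop[cols] <- model$pop_labels[k]
    col0 <- col0 + nd
  }
  colnames(geno) <- paste0(sample_pop, "_", stats::ave(seq_along(sample_pop),
                                                       sample_pop, FUN = seq_along))
  names(sample_pop) <- colnames(geno)

  anc <- ifelse(derived_is_alt, "ref", "alt")
  if (polarization_error > 0) {
    flip <- stats::runif(n) < polarization_error
    anc[flip] <- ifelse(anc[flip] == "ref", "alt", "ref")
  }

  gm <- genotype_matrix("chr09", pos, ref, alt, geno, sample_pop, anc)
  attr(gm, "truth") <- list(p_anc = p_anc, pop_freq = pop_freq,
                            derived_is_alt = derived_is_alt, swept = swept,
                            sweep = sweep, model = model)
  gm
}
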