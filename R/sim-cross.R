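## Biparental-cross simulation: F2 (one meiosis from a fully heterozygous F1,
## as in a near-isogenic F2) and F8 RILs (seven rounds of selfing from the F1,
## leaving residual heterozygosity (1/2)^7 per locus). Segregation distortion
## is modelled as viability selection: each individual survives with
## probability proportional to the product over loci of the genotype-class
## weight, implemented by rejection sampling, so single-locus class
## frequencies follow the Mendelian ratio reweighted and renormalized.

#' Cross configuration
#'
#' @param cross_type `"RIL_F8"` or `"NIL_F2"`.
#' @param n_individuals Number of lines/individuals to produce.
#' @param loci Data frame with columns `name` and `position_bp`, ordered by
#'   position.
#' @param recomb_fraction Recombination fraction between adjacent loci: scalar
#'   or vector of length `nrow(loci) - 1`, each in `[0, 0.5]` (0.5 = free
#'   recombination).
#' @param distortion_weights Relative viability weight per genotype class
#'   (copies of the B-parent allele: 0, 1, 2) at each locus: a list of
#'   length-3 positive vectors, one per locus, or `NULL` for no distortion.
#' @return A `cross_config` list.
#' @export
cross_config <- function(cross_type = c("NIL_F2", "RIL_F8"),
                         n_individuals,
                         loci = data.frame(name = c("IndelI", "SNP3"),
                                           position_bp = c(15273436L, 15274099L)),
                         recomb_fraction = 0.005,
                         distortion_weights = NULL) {
  cross_type <- match.arg(cross_type)
  n_individuals <- check_positive_int(n_individuals, "n_individuals")
  if (!all(c("name", "position_bp") %in% names(loci))) {
    stop_invalid("loci must have columns 'name' and 'position_bp'")
  }
  m <- nrow(loci)
  recomb_fraction <- rep_len(recomb_fraction, max(m - 1L, 1L))
  if (any(recomb_fraction < 0 | recomb_fraction > 0.5)) {
    stop_invalid("recombination fractions must lie in [0, 0.5]")
  }
  if (is.null(distortion_weights)) {
    distortion_weights <- rep(list(c(1, 1, 1)), m)
  }
  if (length(distortion_weights) != m) stop_invalid("one weight triple per locus required")
  for (w in distortion_weights) {
    if (length(w) != 3L || any(w <= 0)) stop_invalid("distortion weights must be three strictly positive values")
  }
  structure(list(cross_type = cross_type, n_individuals = n_individuals,
                 loci = loci, recomb_fraction = recomb_fraction,
                 distortion_weights = distortion_weights),
            class = "cross_config")
}

## One gamete per row of a haplotype pair. h1, h2: n x m matrices of 0/1.
## Adjacent loci recombine with fraction r (vector length m-1).
draw_gametes <- function(h1, h2, r) {
  n <- nrow(h1); m <- ncol(h1)
  src <- matrix(NA_integer_, n, m)
  src[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1) {
    for (j in 2:m) {
      switch_ <- stats::rbinom(n, 1L, r[j - 1])
      src[, j] <- (src[, j - 1] + switch_) %% 2L
    }
  }
  g <- ifelse(src == 0L, h1, h2)
  matrix(g, n, m)
}

## Simulate a batch of n individuals (haplotype pairs) of the requested cross.
simulate_cross_batch <- function(n, m, r, cross_type) {
  ## F1: one all-A (0) and one all-B (1) haplotype
  h1 <- matrix(0L, n, m)
  h2 <- matrix(1L, n, m)
  gens <- if (cross_type == "NIL_F2") 1L else 7L
  for (g in seq_len(gens)) {
    g1 <- draw_gametes(h1, h2, r)
    g2 <- draw_gametes(h1, h2, r)
    h1 <- g1; h2 <- g2
  }
  list(h1 = h1, h2 = h2)
}

#' Simulate a biparental cross
#'
#' Founders are homozygous opposite at all loci (parent A contributes allele
#' 0, parent B allele 1); the cross starts from their fully heterozygous F1.
#' `NIL_F2` performs one meiosis (selfing the F1); `RIL_F8` performs seven
#' successive selfing generations with recombination at each meiosis, so
#' per-locus residual heterozygosity is (1/2)^7 before distortion and linked
#' loci stay correlated for small recombination fractions.
#'
#' @param config A [cross_config()].
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with one column per line/individual and one
#'   row per locus; calls count copies of the B-parent allele. Samples are
#'   labelled with the cross type as their population.
#' @export
simulate_cross <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(seed)
  m <- nrow(config$loci)
  r <- config$recomb_fraction
  wmat <- do.call(rbind, config$distortion_weights)  # m x 3
  wmax <- prod(apply(wmat, 1, max))

  keep1 <- NULL; keep2 <- NULL
  n_needed <- config$n_individuals
  while (n_needed > 0) {
    batch <- simulate_cross_batch(max(n_needed * 2L, 32L), m, r, config$cross_type)
    dosage <- batch$h1 + batch$h2   # n x m in 0:2
    ## viability weight = product over loci of class weight, rejection-sampled
    w <- rep(1, nrow(dosage))
    for (j in seq_len(m)) w <- w * wmat[j, dosage[, j] + 1L]
    acc <- stats::runif(length(w)) < w / wmax
    keep1 <- rbind(keep1, batch$h1[acc, , drop = FALSE])
    keep2 <- rbind(keep2, batch$h2[acc, , drop = FALSE])
    n_needed <- config$n_individuals - nrow(keep1)
  }
  keep1 <- keep1[seq_len(config$n_individuals), , drop = FALSE]
  keep2 <- keep2[seq_len(config$n_individuals), , drop = FALSE]
  dosage <- t(keep1 + keep2)        # m x n: sites x individuals

  ids <- sprintf("%s_%03d", if (config$cross_type == "NIL_F2") "F2" else "RIL",
                 seq_len(config$n_individuals))
  colnames(dosage) <- ids
  sample_pop <- stats::setNames(rep(config$cross_type, length(ids)), ids)
  genotype_matrix("chr09", config$loci$position_bp,
                  ref = rep("A", m), alt = rep("B", m),
                  geno = dosage, sample_pop = sample_pop,
                  anc = rep("unknown", m))
}

#' Expected genotype-class probabilities under single-locus distortion
#'
#' Closed-form check used by the tests: Mendelian F2 class probabilities
#' (1/4, 1/2, 1/4) reweighted by the viability weights and renormalized.
#'
#' @param weights Length-3 positive vector of class weights (0, 1, 2 copies).
#' @return Length-3 probability vector.
#' @export
f2_expected_class_probs <- function(weights) {
  if (length(weights) != 3L || any(weights <= 0)) {
    stop_invalid("weights must be three strictly positive values")
  }
  p <- c(0.25, 0.5, 0.25) * weights
  p / sum(p)
}
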