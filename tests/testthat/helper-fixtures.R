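# Fixture builders shared across the suite. Everything is generated in code;
# no binary data.

# Genotype matrix with exact per-population allele-dosage columns.
# freqs: list of per-population dosage vectors (sites x samples), or a
# function of (pop, n_samples) returning a matrix.
toy_matrix <- function(pos, geno_by_pop, ref = NULL, alt = NULL, anc = NULL) {
  pops <- names(geno_by_pop)
  geno <- do.call(cbind, geno_by_pop)
  sample_pop <- unlist(lapply(pops, function(p) {
    rep(p, ncol(geno_by_pop[[p]]))
  }))
  colnames(geno) <- paste0(sample_pop, "_", seq_along(sample_pop))
  names(sample_pop) <- colnames(geno)
  n <- length(pos)
  genotype_matrix("chr09", pos,
                  ref = ref %||% rep("A", n), alt = alt %||% rep("T", n),
                  geno = geno, sample_pop = sample_pop,
                  anc = anc %||% rep("unknown", n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A matrix whose population allele frequencies are (close to) the requested
# values, built from deterministic dosage counts on 2*n chromosomes.
matrix_from_freqs <- function(pos, freq_by_pop, n_diploids = 10, anc = NULL) {
  geno_by_pop <- lapply(freq_by_pop, function(fv) {
    t(vapply(fv, function(f) {
      alt_copies <- round(f * 2 * n_diploids)
      g <- integer(n_diploids)
      g[seq_len(alt_copies %/% 2)] <- 2L
      if (alt_copies %% 2 == 1) g[alt_copies %/% 2 + 1L] <- 1L
      g
    }, integer(n_diploids)))
  })
  toy_matrix(pos, geno_by_pop, anc = anc)
}

# Textbook oracles (independent of the package implementation paths).
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

oracle_chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

oracle_gof_chisq <- function(obs, ratio) {
  exp <- sum(obs) * ratio / sum(ratio)
  sum((obs - exp)^2 / exp)
}

oracle_pearson_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
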