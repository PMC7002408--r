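#' Biallelic SNP genotype matrix with population labels
#'
#' The central in-memory container of the pipeline: biallelic SNPs (rows) by
#' samples (columns), with 1-based positions on a single chromosome, REF/ALT
#' alleles, an ancestral-state annotation per site and a population label per
#' sample. Genotype calls count copies of the ALT allele (0, 1, 2; `NA` for
#' missing).
#'
#' @param chrom Single chromosome name.
#' @param pos Integer vector of 1-based positions, strictly increasing.
#' @param ref,alt Character vectors of REF/ALT alleles (single bases).
#' @param geno Integer matrix, sites x samples, values in `0:2` or `NA`.
#' @param sample_pop Named character vector: population label per sample; names
#'   must match `colnames(geno)`.
#' @param anc Character vector per site, one of `"ref"`, `"alt"`, `"unknown"`:
#'   which allele is ancestral (outgroup-polarized truth where available).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, sample_pop,
                            anc = rep("unknown", length(pos))) {
  if (length(chrom) != 1L) stop_invalid("a genotype_matrix holds a single chromosome")
  pos <- as.integer(pos)
  if (is.unsorted(pos, strictly = TRUE)) stop_invalid("positions must be strictly increasing")
  n <- length(pos)
  geno <- as.matrix(geno)
  if (nrow(geno) != n) stop_invalid("geno must have one row per site")
  if (length(ref) != n || length(alt) != n || length(anc) != n) {
    stop_invalid("ref, alt and anc must have one entry per site")
  }
  if (!all(anc %in% c("ref", "alt", "unknown"))) {
    stop_invalid("anc entries must be 'ref', 'alt' or 'unknown'")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) stop_invalid("genotype calls must be 0, 1, 2 or NA")
  if (is.null(colnames(geno))) colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  if (is.null(names(sample_pop))) names(sample_pop) <- colnames(geno)
  if (!setequal(names(sample_pop), colnames(geno)) ||
      length(sample_pop) != ncol(geno)) {
    stop_invalid("every sample needs exactly one population label")
  }
  sample_pop <- sample_pop[colnames(geno)]
  structure(
    list(chrom = chrom, pos = pos, ref = as.character(ref), alt = as.character(alt),
         anc = as.character(anc), geno = geno,
         sample_pop = sample_pop),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %s\n",
              length(x$pos), ncol(x$geno), x$chrom))
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$sample_pop)),
                                    table(x$sample_pop)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Population names of a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Character vector of distinct population labels, in order of first
#'   appearance among the samples.
#' @export
populations <- function(gm) unique(unname(gm$sample_pop))

#' Per-population ALT-allele frequencies
#'
#' Allele frequencies are computed from non-missing calls only; a site with no
#' calls in a population gets `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param pops Populations to compute (default: all).
#' @return Numeric matrix, sites x populations, of ALT-allele frequencies.
#' @export
pop_allele_freqs <- function(gm, pops = populations(gm)) {
  out <- vapply(pops, function(p) {
    g <- gm$geno[, gm$sample_pop == p, drop = FALSE]
    n_called <- rowSums(!is.na(g))
    rowSums(g, na.rm = TRUE) / (2 * n_called)
  }, numeric(length(gm$pos)))
  out <- matrix(out, nrow = length(gm$pos), dimnames = list(NULL, pops))
  out
}

#' Derived-allele frequencies from recorded ancestral states
#'
#' Uses the per-site `anc` annotation (e.g. the simulator's truth, or the `AA`
#' INFO tag of a VCF). Sites with unknown ancestral state get `NA`.
#'
#' @inheritParams pop_allele_freqs
#' @return Numeric matrix, sites x populations, of derived-allele frequencies.
#' @export
derived_allele_freqs <- function(gm, pops = populations(gm)) {
  alt <- pop_allele_freqs(gm, pops)
  flip <- gm$anc == "alt"
  unknown <- gm$anc == "unknown"
  alt[flip, ] <- 1 - alt[flip, , drop = FALSE]
  alt[unknown, ] <- NA_real_
  alt
}
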