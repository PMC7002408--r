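## Derived allele-frequency spectra around a focal mutation. A hard sweep
## drags linked derived variants to high frequency, producing an excess of
## low- and high-frequency derived alleles (a U-shaped AFS) whose strength
## decays with recombination distance from the selected site; the decay is
## quantified by two-sample Kolmogorov-Smirnov tests of each distance bin
## against the genome background.

#' Polarize sites against an outgroup population
#'
#' The ancestral allele of a site is the outgroup's major allele, accepted
#' when the outgroup major-allele frequency is at least `major_cutoff`
#' (monomorphic outgroup included); sites with a too-polymorphic or fully
#' missing outgroup are excluded (count reported via message). The derived
#' frequency is 1 minus the ancestral-allele frequency in the focal
#' population.
#'
#' @param gm A [genotype_matrix()].
#' @param focal_pop Population whose derived spectrum is wanted.
#' @param outgroup_pop Outgroup population used for polarization.
#' @param major_cutoff Minimum outgroup major-allele frequency (default 0.9).
#' @return Data frame `pos`, `ancestral` ("ref"/"alt"), `derived_freq`
#'   (in the focal population) for the retained sites, with the number of
#'   excluded sites in attribute `n_excluded`.
#' @export
polarize_derived <- function(gm, focal_pop, outgroup_pop, major_cutoff = 0.9) {
  pops <- populations(gm)
  if (!outgroup_pop %in% pops) stop_invalid("outgroup population '%s' not present", outgroup_pop)
  if (!focal_pop %in% pops) stop_invalid("focal population '%s' not present", focal_pop)
  freq <- pop_allele_freqs(gm, c(focal_pop, outgroup_pop))
  og <- freq[, 2]
  usable <- !is.na(og) & pmax(og, 1 - og) >= major_cutoff
  n_excluded <- sum(!usable)
  if (!any(usable)) stop_invalid("no usable sites after outgroup polarization")
  if (n_excluded > 0) {
    message(sprintf("polarize_derived: %d site(s) excluded (polymorphic or missing outgroup)",
                    n_excluded))
  }
  ancestral <- ifelse(og[usable] >= 0.5, "alt", "ref")
  focal <- freq[usable, 1]
  derived_freq <- ifelse(ancestral == "alt", 1 - focal, focal)
  out <- data.frame(pos = gm$pos[usable], ancestral = ancestral,
                    derived_freq = derived_freq)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Distance-binned derived spectra around a focal position
#'
#' Bin k collects segregating polarized sites at distances in
#' `((k-1)*bin, k*bin]` from the focal position (so a site exactly at 10 kb
#' belongs to the 10-kb bin), up/downstream combined by default. Sites with
#' derived frequency 0 or 1 are excluded; empty bins are reported with
#' `n_snps = 0`.
#'
#' @param polarized Output of [polarize_derived()].
#' @param focal_position Focal position (1-based bp).
#' @param max_distance Maximum distance covered (default 80 kb).
#' @param bin Bin width in bp (default 10 kb); must be positive.
#' @param side `"combined"` (default), `"upstream"` or `"downstream"`.
#' @return List of class `spectrum_windows`; each element has
#'   `distance_bin_bp` (upper edge of the bin), `side`, `derived_freqs`,
#'   `n_snps`.
#' @export
distance_binned_spectra <- function(polarized, focal_position,
                                    max_distance = 80000, bin = 10000,
                                    side = c("combined", "upstream", "downstream")) {
  side <- match.arg(side)
  if (bin <= 0) stop_invalid("bin width must be positive")
  seg <- polarized$derived_freq > 0 & polarized$derived_freq < 1
  df <- polarized[seg, , drop = FALSE]
  if (side == "upstream") df <- df[df$pos < focal_position, , drop = FALSE]
  if (side == "downstream") df <- df[df$pos > focal_position, , drop = FALSE]
  d <- abs(df$pos - focal_position)
  keep <- d > 0 & d <= max_distance
  df <- df[keep, , drop = FALSE]; d <- d[keep]
  k <- ceiling(d / bin)             # ((k-1)*bin, k*bin]
  n_bins <- ceiling(max_distance / bin)
  out <- lapply(seq_len(n_bins), function(kk) {
    f <- df$derived_freq[k == kk]
    list(distance_bin_bp = kk * bin, side = side,
         derived_freqs = f, n_snps = length(f))
  })
  structure(out, class = "spectrum_windows")
}

#' U-shape index of a derived spectrum
#'
#' Convenience summary (not a test): the proportion of sites with derived
#' frequency at or below `tail` or at or above `1 - tail`. Invariant under
#' the reflection `f -> 1 - f`. Undefined (NA) for an empty spectrum.
#'
#' @param freqs Numeric vector of derived frequencies, or one element of a
#'   [distance_binned_spectra()] result.
#' @param tail Tail width (default 0.1).
#' @return Proportion in `[0, 1]`, or `NA` if empty.
#' @export
u_shape_index <- function(freqs, tail = 0.1) {
  if (is.list(freqs)) freqs <- freqs$derived_freqs
  if (length(freqs) == 0) return(NA_real_)
  mean(freqs <= tail | freqs >= 1 - tail)
}

#' Kolmogorov-Smirnov distance-decay test
#'
#' Compares each distance bin's derived spectrum with the genome background
#' (derived frequencies of segregating sites outside the focal region) by a
#' two-sample KS test (asymptotic P), and summarizes decay as the Spearman
#' rank correlation between bin distance and KS D: a negative correlation
#' means the spectrum distortion decays with distance, the hitch-hiking
#' signature. Bins with fewer than `min_n` sites are flagged and not tested.
#'
#' @param spectra A [distance_binned_spectra()] result.
#' @param background_freqs Derived frequencies of background SNPs (segregating
#'   sites genome-wide excluding the focal region); must be non-empty.
#' @param min_n Minimum bin size to test (default 5).
#' @return List with `bins` (data frame `distance_bin_bp`, `side`, `n_snps`,
#'   `n_background`, `u_shape_index`, `ks_D`, `ks_p`, `tested`) and `decay`
#'   (list `spearman_rho`, `p`).
#' @export
ks_decay_test <- function(spectra, background_freqs, min_n = 5) {
  background_freqs <- background_freqs[background_freqs > 0 & background_freqs < 1]
  if (length(background_freqs) == 0) stop_invalid("background frequency set is empty")
  rows <- lapply(spectra, function(sw) {
    tested <- sw$n_snps >= min_n
    if (tested) {
      kt <- suppressWarnings(stats::ks.test(sw$derived_freqs, background_freqs))
      D <- unname(kt$statistic); p <- kt$p.value
    } else {
      D <- NA_real_; p <- NA_real_
    }
    data.frame(distance_bin_bp = sw$distance_bin_bp, side = sw$side,
               n_snps = sw$n_snps, n_background = length(background_freqs),
               u_shape_index = u_shape_index(sw), ks_D = D, ks_p = p,
               tested = tested)
  })
  bins <- do.call(rbind, rows)
  ok <- bins$tested
  decay <- list(spearman_rho = NA_real_, p = NA_real_)
  if (sum(ok) >= 3) {
    ct <- suppressWarnings(stats::cor.test(bins$distance_bin_bp[ok], bins$ks_D[ok],
                                           method = "spearman"))
    decay <- list(spearman_rho = unname(ct$estimate), p = ct$p.value)
  }
  list(bins = bins, decay = decay)
}

#' Background derived frequencies for the decay test
#'
#' Helper extracting segregating derived frequencies of polarized sites
#' outside `focal_position +/- max_distance`.
#'
#' @inheritParams distance_binned_spectra
#' @return Numeric vector of background derived frequencies.
#' @export
background_derived_freqs <- function(polarized, focal_position, max_distance = 80000) {
  far <- abs(polarized$pos - focal_position) > max_distance
  f <- polarized$derived_freq[far]
  f[f > 0 & f < 1]
}
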