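## Nei (GST-form) FST and the windowed genome scan.

#' Per-site Nei FST between two populations
#'
#' Nei's GST computed from allele frequencies: `HT = 2*pbar*(1-pbar)` with
#' `pbar` the unweighted mean of the two population frequencies,
#' `HS = mean(2*p_i*(1-p_i))`, `FST = (HT - HS)/HT`. A site monomorphic in
#' both populations (`HT = 0`) has FST defined as 0 and is flagged
#' non-segregating. No sample-size correction is applied, so FST lies in
#' `[0, 1]` by construction. Vectorized over sites.
#'
#' @param p1,p2 Allele frequencies in the two populations, each in `[0, 1]`
#'   (the same allele in both; the statistic is invariant to relabelling
#'   `p -> 1 - p` in both populations, and symmetric in its arguments).
#' @return Data frame with columns `p1`, `p2`, `HT`, `HS`, `fst`,
#'   `segregating`.
#' @export
site_fst <- function(p1, p2) {
  check_prob(p1, "p1"); check_prob(p2, "p2")
  pbar <- (p1 + p2) / 2
  HT <- 2 * pbar * (1 - pbar)
  HS <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  fst <- ifelse(HT == 0, 0, (HT - HS) / HT)
  data.frame(p1 = p1, p2 = p2, HT = HT, HS = HS, fst = fst,
             segregating = HT > 0)
}

## Bare vectorized FST values (internal fast path).
fst_nei <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  HT <- 2 * pbar * (1 - pbar)
  HS <- p1 * (1 - p1) + p2 * (1 - p2)
  ifelse(HT == 0, 0, (HT - HS) / HT)
}

#' Sliding-window mean FST
#'
#' Windows are anchored at coordinate 0 and tile the chromosome at the given
#' step: window j spans `[start, start + window)` with
#' `start = (j - 1) * step`, for `floor((L - window)/step) + 1` windows. The
#' window statistic is the unweighted mean of per-site FST over the SNPs the
#' window contains; empty windows are reported with `n_snps = 0` and a
#' missing mean.
#'
#' @param sites Data frame with columns `pos` (sorted, 1-based) and `fst`.
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 20 kb).
#' @param step Step size in bp (default 2 kb); `step > window` is a
#'   configuration error (SNPs would fall in gaps).
#' @param chrom Chromosome name for the output.
#' @return Data frame `chrom`, `start` (0-based), `end` (exclusive),
#'   `window_index`, `n_snps`, `mean_fst`.
#' @export
window_fst <- function(sites, chrom_length, window = 20000, step = 2000,
                       chrom = "chr") {
  if (step > window) stop_invalid("step (%d) must not exceed window (%d)", step, window)
  if (is.unsorted(sites$pos)) stop_invalid("sites must be sorted by position")
  starts <- seq(0L, by = as.integer(step),
                length.out = floor((chrom_length - window) / step) + 1)
  pos <- sites$pos
  cs <- c(0, cumsum(sites$fst))
  ## window [start, start + window) contains pos with start <= pos < start+window
  lo <- findInterval(starts - 0.5, pos)         # sites with pos < start
  hi <- findInterval(starts + window - 0.5, pos) # sites with pos < start+window
  n <- hi - lo
  mean_fst <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
  data.frame(chrom = chrom, start = starts, end = starts + window,
             window_index = seq_along(starts), n_snps = n, mean_fst = mean_fst)
}

#' Top-quantile threshold and flagging
#'
#' Flags all values at or above the empirical `(1 - q)` quantile (ties at the
#' threshold are all included). Used for the genome-wide top 5 per-mille
#' window call and the top 5% PBS call.
#'
#' @param values Numeric vector (NAs ignored; all-missing is an error).
#' @param q Upper tail mass, in (0, 1).
#' @return List with `threshold` and logical `flagged` (same length as
#'   `values`; `NA` values are never flagged).
#' @export
top_quantile_threshold <- function(values, q) {
  if (q <= 0 || q >= 1) stop_invalid("q must lie in (0, 1)")
  ok <- !is.na(values)
  if (!any(ok)) stop_invalid("no finite values to threshold")
  thr <- stats::quantile(values[ok], probs = 1 - q, names = FALSE, type = 7)
  flagged <- !is.na(values) & values >= thr
  list(threshold = thr, flagged = flagged)
}
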