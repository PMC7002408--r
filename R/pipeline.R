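## Orchestration: simulate (or read) -> windowed scan -> gene PBS/HKA ->
## candidates -> AFS decay report, and the association pipeline, each driven
## by a single config list and a seed, writing TSVs with provenance headers.

validate_scan_config <- function(config) {
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop_invalid("config must contain exactly one of 'simulation' or 'inputs'")
  }
  if (is.null(config$out_dir)) stop_invalid("config$out_dir is required")
  if (is.null(config$target_pop)) stop_invalid("config$target_pop is required")
  invisible(config)
}

## Evenly spaced synthetic gene models used when a simulation config does not
## supply an annotation: n_genes genes of gene_length bp, uniformly spaced.
tiling_genes <- function(chrom, chrom_length, n_genes, gene_length = 4000) {
  spacing <- floor(chrom_length / n_genes)
  start <- (seq_len(n_genes) - 1L) * spacing + 1L
  data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
             chrom = chrom, start = start, end = start + gene_length - 1L,
             strand = "+", stringsAsFactors = FALSE)
}

#' Run the selection-scan pipeline
#'
#' Stages: obtain genotypes (simulate from `config$simulation`, or read
#' `config$inputs$vcf` + `config$inputs$pops` + `config$inputs$genes`),
#' windowed FST scan between target and sister populations, per-gene
#' FST/PBS/HKA statistics, sweep-candidate calling, and (when a focal locus
#' is configured) the AFS distance-decay report. All tables are written under
#' `config$out_dir` with provenance headers (tool version, seed, config
#' hash); partially written outputs are removed on failure.
#'
#' @param config List with fields: exactly one of `simulation` (list with
#'   `model` = [population_model()], optional `sweep` = [sweep_config()],
#'   optional `genes`, optional `n_genes`/`gene_length`) or `inputs` (list
#'   `vcf`, `pops`, `genes` paths); `target_pop`; optional `sister_pop`,
#'   `outgroup_pop` (defaults: second and third population); optional
#'   `thresholds` = [scan_thresholds()]; optional `focal` (list `position`,
#'   `max_distance`, `bin`); optional `window`, `step`; `out_dir`.
#' @param seed Integer seed for the simulation path.
#' @return Invisible list with `windows`, `gene_stats`, `candidates`, `afs`
#'   (or NULL), and the output paths.
#' @export
run_scan_pipeline <- function(config, seed = 1L) {
  validate_scan_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c(windows = "windows.tsv", genes = "genes.tsv",
                       candidates = "candidates.tsv", afs = "afs.tsv",
                       log = "run.log"))
  names(paths) <- c("windows", "genes", "candidates", "afs", "log")
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    chash <- config_hash(config[setdiff(names(config), "out_dir")])
    logf <- file(paths["log"], "w")
    on.exit(close(logf), add = TRUE)
    written <- c(written, paths["log"])
    logmsg <- function(...) {
      msg <- sprintf(...)
      writeLines(msg, logf)
      message(msg)
    }
    logmsg("tillersweep %s scan; seed=%d; config=%s", pkg_version_string(), seed, chash)

    thresholds <- config$thresholds %||% scan_thresholds()
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      gm <- simulate_three_pop_genotypes(sim$model, sim$sweep, seed = seed)
      genes <- sim$genes %||% tiling_genes(gm$chrom, sim$model$chrom_length_bp,
                                           sim$n_genes %||% 250L,
                                           sim$gene_length %||% 4000L)
      chrom_length <- sim$model$chrom_length_bp
    } else {
      gm <- read_vcf(config$inputs$vcf, read_pop_map(config$inputs$pops))
      genes <- read_genes(config$inputs$genes)
      chrom_length <- config$chrom_length %||% max(gm$pos)
    }
    pops <- populations(gm)
    target <- config$target_pop
    sister <- config$sister_pop %||% setdiff(pops, target)[1]
    logmsg("genotypes: %d sites x %d samples; pops: %s",
           length(gm$pos), ncol(gm$geno), paste(pops, collapse = ", "))

    ## windowed FST scan target vs sister
    freq <- pop_allele_freqs(gm, c(target, sister))
    sites <- data.frame(pos = gm$pos, fst = fst_nei(freq[, 1], freq[, 2]))
    windows <- window_fst(sites, chrom_length,
                          window = config$window %||% 20000,
                          step = config$step %||% 2000, chrom = gm$chrom)
    tqw <- top_quantile_threshold(windows$mean_fst, thresholds$window_quantile)
    windows$flagged <- tqw$flagged
    write_window_stats(windows, paths["windows"], seed = seed, config_hash = chash)
    written <- c(written, paths["windows"])
    logmsg("windows: %d (%d flagged at top %.3f%%)", nrow(windows),
           sum(windows$flagged), 100 * thresholds$window_quantile)

    ## per-gene PBS/HKA
    gene_stats <- gene_fst_and_counts(gm, genes, target,
                                      fixation_fst_cutoff = thresholds$fixation_fst_cutoff,
                                      pbs_mode = config$pbs_mode %||% "standard")
    gene_stats <- hka_scan(gene_stats)
    cand <- sweep_candidates(gene_stats, thresholds)
    gene_stats <- attr(cand, "gene_stats")
    write_stats_tsv(gene_stats, paths["genes"], seed = seed, config_hash = chash)
    write_stats_tsv(as.data.frame(cand), paths["candidates"], seed = seed,
                    config_hash = chash)
    written <- c(written, paths["genes"], paths["candidates"])
    logmsg("genes: %d; candidates (PBS top %.0f%% and HKA p < %.2f): %d",
           nrow(gene_stats), 100 * thresholds$pbs_quantile, thresholds$hka_alpha,
           nrow(cand))

    ## AFS decay report around the focal locus
    afs <- NULL
    if (!is.null(config$focal)) {
      outgroup <- config$outgroup_pop %||% setdiff(pops, c(target, sister))[1]
      pol <- polarize_derived(gm, target, outgroup)
      spec <- distance_binned_spectra(pol, config$focal$position,
                                      max_distance = config$focal$max_distance %||% 80000,
                                      bin = config$focal$bin %||% 10000)
      bg <- background_derived_freqs(pol, config$focal$position,
                                     config$focal$max_distance %||% 80000)
      ks <- ks_decay_test(spec, bg)
      afs <- ks
      write_stats_tsv(ks$bins, paths["afs"], seed = seed, config_hash = chash)
      written <- c(written, paths["afs"])
      logmsg("AFS decay: spearman rho = %.3f (p = %.3g)",
             ks$decay$spearman_rho, ks$decay$p)
    }
    invisible(list(windows = windows, gene_stats = gene_stats,
                   candidates = cand, afs = afs, paths = paths))
  }, error = on_fail)
}

#' Run the association pipeline
#'
#' Stages: obtain a cross genotype matrix and phenotypes (simulate from
#' `config$simulation` -- a [cross_config()] plus [phenotype_model()] -- or
#' read `config$inputs$pheno` and a site x accession genotype TSV), run the
#' [association_table()] for the configured plan, and the
#' [segregation_test()]s. Outputs under `config$out_dir`.
#'
#' @param config List with fields: exactly one of `simulation` (list `cross`
#'   = [cross_config()], `phenotype` = [phenotype_model()]) or `inputs`
#'   (list `pheno`, `geno` paths; `geno` a TSV of accessions x site dosage
#'   columns with a `line_id` column); `plan` as in [association_table()];
#'   optional `segregation` (list per locus: `classes` to count and
#'   `expected_ratio`); `out_dir`.
#' @param seed Integer seed for the simulation path.
#' @return Invisible list with `association`, `segregation`, paths.
#' @export
run_association_pipeline <- function(config, seed = 1L) {
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop_invalid("config must contain exactly one of 'simulation' or 'inputs'")
  }
  if (is.null(config$out_dir)) stop_invalid("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(association = file.path(config$out_dir, "association.tsv"),
             segregation = file.path(config$out_dir, "segregation.tsv"))
  written <- character(0)
  tryCatch({
    chash <- config_hash(config[setdiff(names(config), "out_dir")])
    if (has_sim) {
      cross <- simulate_cross(config$simulation$cross, seed = seed)
      geno <- t(cross$geno)
      colnames(geno) <- config$simulation$cross$loci$name
      pheno <- simulate_phenotypes(geno, config$simulation$phenotype, seed = seed + 1L)
    } else {
      pheno <- read_phenotypes(config$inputs$pheno)
      gdf <- utils::read.delim(config$inputs$geno, comment.char = "#",
                               stringsAsFactors = FALSE)
      if (!"line_id" %in% names(gdf)) stop_invalid("genotype TSV needs a line_id column")
      geno <- as.matrix(gdf[, setdiff(names(gdf), "line_id"), drop = FALSE])
      rownames(geno) <- gdf$line_id
    }
    assoc <- association_table(pheno, geno, config$plan)
    write_stats_tsv(assoc, paths["association"], seed = seed, config_hash = chash)
    written <- c(written, paths["association"])

    seg <- NULL
    if (!is.null(config$segregation)) {
      seg_rows <- lapply(names(config$segregation), function(locus) {
        sc <- config$segregation[[locus]]
        counts <- vapply(sc$classes, function(cl) sum(geno[, locus] == cl, na.rm = TRUE),
                         integer(1))
        st <- segregation_test(counts, sc$expected_ratio, locus = locus)
        data.frame(locus = locus,
                   classes = paste(sc$classes, collapse = ":"),
                   observed = paste(counts, collapse = ":"),
                   expected_ratio = paste(sc$expected_ratio, collapse = ":"),
                   chi2 = st$chi2, df = st$df, p = st$p, stringsAsFactors = FALSE)
      })
      seg <- do.call(rbind, seg_rows)
      write_stats_tsv(seg, paths["segregation"], seed = seed, config_hash = chash)
      written <- c(written, paths["segregation"])
    }
    invisible(list(association = assoc, segregation = seg, paths = paths))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}
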