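## Readers and writers for the standard formats the pipeline touches.
## Coordinate contract: in-memory, VCF and GFF are 1-based inclusive; the
## window table on disk is BED-like, 0-based half-open. No statistics here.

#' Read a biallelic-SNP VCF into a genotype matrix
#'
#' Supports the VCF 4.2 subset the pipeline emits: single chromosome, GT
#' genotypes, optional `AA` INFO tag carrying the ancestral allele.
#' Multiallelic and non-SNP records are skipped (counts reported via a
#' message); missing GT becomes a missing call.
#'
#' @param path Path to a VCF file.
#' @param sample_pop_map Named character vector mapping sample name to
#'   population, or a data frame with columns `sample` and `pop` (e.g. from
#'   [read_pop_map()]).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_pop_map) {
  if (!file.exists(path)) stop_invalid("VCF file not found: %s", path)
  if (is.data.frame(sample_pop_map)) {
    sample_pop_map <- stats::setNames(as.character(sample_pop_map$pop),
                                      sample_pop_map$sample)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop_invalid("no parsable records in %s", path)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")      # multiallelic ALT contains ','
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message(sprintf("read_vcf: skipped %d multiallelic/non-SNP record(s)", n_skipped))
  }
  if (!any(snp)) stop_invalid("no biallelic SNP records in %s", path)
  if (length(unique(fix$CHROM[snp])) > 1L) {
    stop_invalid("multiple chromosomes in %s; one chromosome per matrix is supported", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  samples <- colnames(gt)
  missing_map <- setdiff(samples, names(sample_pop_map))
  if (length(missing_map)) {
    stop_invalid("sample(s) absent from the population map: %s",
                 paste(missing_map, collapse = ", "))
  }
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- apply(gt, 2, code)
  geno <- matrix(geno, ncol = length(samples), dimnames = list(NULL, samples))

  aa <- vcfR::extract.info(v, "AA")[snp]
  ref <- fix$REF[snp]; alt <- fix$ALT[snp]
  anc <- rep("unknown", sum(snp))
  anc[!is.na(aa) & aa == ref] <- "ref"
  anc[!is.na(aa) & aa == alt] <- "alt"

  gm <- genotype_matrix(chrom = fix$CHROM[snp][1],
                        pos = as.integer(fix$POS[snp]),
                        ref = ref, alt = alt, geno = geno,
                        sample_pop = sample_pop_map[samples], anc = anc)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits the subset read back by [read_vcf()]: `QUAL="."`, `FILTER="PASS"`,
#' `INFO` carrying `AA=<ancestral allele>` where known, unphased GT.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=tillersweep_%s", pkg_version_string()),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gm$geno)), collapse = "\t")), con)
  info <- ifelse(gm$anc == "ref", paste0("AA=", gm$ref),
                 ifelse(gm$anc == "alt", paste0("AA=", gm$alt), "."))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = nrow(gm$geno))
  gt_str[is.na(gm$geno)] <- "./."
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", info, "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read / write a sample-to-population map
#'
#' Two-column TSV (`sample`, `pop`), header required, `#` comments allowed.
#'
#' @param path File path.
#' @return Data frame with columns `sample`, `pop`.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample", "pop") %in% names(df))) {
    stop_invalid("population map %s must have columns 'sample' and 'pop'", path)
  }
  df
}

#' @rdname read_pop_map
#' @param gm A [genotype_matrix()] whose labels are written.
#' @export
write_pop_map <- function(gm, path) {
  df <- data.frame(sample = names(gm$sample_pop), pop = unname(gm$sample_pop))
  write_stats_tsv(df, path)
}

#' Read a phenotype table
#'
#' TSV with columns `line_id`, `timepoint`, `trait`, `value`; `#` comments
#' allowed. Duplicated (line, timepoint, trait) rows are averaged with a
#' warning. Non-numeric values are an error reporting the offending line
#' numbers.
#'
#' @param path File path.
#' @param timepoints Optional allowed timepoint labels; an unknown label is a
#'   configuration error.
#' @return Data frame `line_id`, `timepoint`, `trait`, `value`.
#' @export
read_phenotypes <- function(path, timepoints = NULL) {
  if (!file.exists(path)) stop_invalid("phenotype file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("line_id", "timepoint", "trait", "value")
  if (!all(need %in% names(df))) {
    stop_invalid("phenotype file %s must have columns %s", path,
                 paste(need, collapse = ", "))
  }
  vals <- suppressWarnings(as.numeric(df$value))
  if (anyNA(vals)) {
    stop_invalid("non-numeric phenotype value(s) at data row(s): %s",
                 paste(which(is.na(vals)), collapse = ", "))
  }
  df$value <- vals
  if (!is.null(timepoints) && !all(df$timepoint %in% timepoints)) {
    stop_invalid("unknown timepoint label(s): %s",
                 paste(setdiff(df$timepoint, timepoints), collapse = ", "))
  }
  key <- paste(df$line_id, df$timepoint, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("read_phenotypes: %d duplicated (line, timepoint, trait) row(s) averaged",
                    sum(duplicated(key))))
    df <- stats::aggregate(value ~ line_id + timepoint + trait, data = df, FUN = mean)
  }
  df[, need]
}

#' Read gene/coding-interval annotation
#'
#' Accepts GFF3 (CDS features grouped by gene identifier: `gene_id`, else
#' `Parent`, else `ID` attribute) or BED (4+ columns; the name field is the
#' gene id; BED's 0-based half-open coordinates are converted to 1-based
#' inclusive). Overlapping intervals of a gene are merged.
#'
#' @param path File path ending in `.gff`/`.gff3` or `.bed`.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive; one row per merged interval).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop_invalid("gene annotation not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    if (length(gr) == 0) stop_invalid("no CDS features in %s", path)
    ids <- if (!is.null(gr$gene_id)) {
      as.character(gr$gene_id)
    } else if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0)) {
      vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    } else {
      as.character(gr$ID)
    }
    if (anyNA(ids)) stop_invalid("CDS feature(s) without a gene identifier in %s", path)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) stop_invalid("no records in %s", path)
    ids <- gr$name
    if (is.null(ids) || anyNA(ids)) stop_invalid("BED gene file %s needs a name column", path)
  } else {
    stop_invalid("unsupported gene annotation format: .%s", ext)
  }
  out <- lapply(split(gr, ids), function(g) {
    red <- GenomicRanges::reduce(g, ignore.strand = TRUE)
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red),
               strand = as.character(GenomicRanges::strand(g))[1],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, Map(cbind, gene_id = names(out), out))
  rownames(df) <- NULL
  df[order(df$chrom, df$start), c("gene_id", "chrom", "start", "end", "strand")]
}

#' Write / read the windowed-scan table
#'
#' BED-like TSV: `chrom`, `start` (0-based), `end` (exclusive), `n_snps`,
#' `mean_fst`, `flagged`; a `#` provenance header carries the tool version
#' and seed.
#'
#' @param path File path.
#' @param windows Data frame from [window_fst()] (1-based in memory; the
#'   on-disk coordinates are 0-based half-open, identical values since
#'   [window_fst()] anchors windows at coordinate 0).
#' @param seed,config_hash Optional provenance fields.
#' @return `path` invisibly (writer); the windows data frame (reader).
#' @export
write_window_stats <- function(windows, path, seed = NULL, config_hash = NULL) {
  write_stats_tsv(windows, path, seed = seed, config_hash = config_hash)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "n_snps")
  if (!all(need %in% names(df))) {
    stop_invalid("window table %s lacks required columns", path)
  }
  df
}

#' Write simulation truth as JSON
#'
#' Dumps the parameters and causal information of a simulated dataset
#' (ancestral-frequency law, drift, sweep and causal loci) for recovery
#' tests.
#'
#' @param gm A simulated [genotype_matrix()] carrying a `"truth"` attribute.
#' @param path Output path.
#' @export
write_truth_json <- function(gm, path) {
  truth <- attr(gm, "truth")
  if (is.null(truth)) stop_invalid("matrix has no simulation truth attached")
  out <- list(model = unclass(truth$model),
              sweep = if (!is.null(truth$sweep)) unclass(truth$sweep),
              n_swept_sites = sum(truth$swept))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
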