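#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study data.
#
# A 5-Mb chromosome segment for three rice populations (upland japonica =
# sweep target, irrigated japonica = sister, indica = outgroup) with a strong
# selective sweep implanted at the center of a known gene, written as VCF +
# population map + gene BED + truth JSON; plus the two segregating
# populations of the association study (an F8 RIL panel of 134 lines and a
# near-isogenic F2 of 451 individuals segregating two linked loci with
# viability distortion) and their tiller-number phenotypes at 40 and 50 DAG.

suppressPackageStartupMessages(library(tillersweep))

seed <- 42L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## --- population genomes ----------------------------------------------------
model <- population_model()                      # 3 x 40 diploids, 5 Mb, 50k SNPs
genes <- tillersweep:::tiling_genes("chr09", model$chrom_length_bp, 250)
focal_gene <- 125L
focal <- (genes$start[focal_gene] + genes$end[focal_gene]) %/% 2L
sweep <- sweep_config(focal, target_pop = "upland_jap")

gm <- simulate_three_pop_genotypes(model, sweep, seed = seed)
write_vcf(gm, file.path(out, "three_pops.vcf"))
write_pop_map(gm, file.path(out, "pops.tsv"))
write_truth_json(gm, file.path(out, "truth.json"))
writeLines(sprintf("chr09\t%d\t%d\t%s", genes$start - 1L, genes$end, genes$gene_id),
           file.path(out, "genes.bed"))
cat(sprintf("simulated %d SNPs x %d samples; sweep implanted in %s (focal pos %d)\n",
            length(gm$pos), ncol(gm$geno), genes$gene_id[focal_gene], focal))

## --- segregating populations ----------------------------------------------
loci <- data.frame(name = c("IndelI", "SNP3"), position_bp = c(15273436L, 15274099L))

## Viability distortion acts at the SNP3 locus; Indel I mirrors it through
## linkage (per-locus weights would compound multiplicatively under tight
## linkage). The F2 weights target the skewed 135:256:60 homozygote pattern.
## Recombination fractions are loosened relative to the ~700-bp physical
## separation of the real variants so that the conditional-analysis cells
## (one locus varying within the other's homozygote class) are populated at
## desk scale.
ril <- simulate_cross(cross_config("RIL_F8", n_individuals = 134, loci = loci,
                                   recomb_fraction = 0.15,
                                   distortion_weights = list(c(1, 1, 1),
                                                             c(1, 0.5, 0.12))),
                      seed = seed + 1L)
f2 <- simulate_cross(cross_config("NIL_F2", n_individuals = 451, loci = loci,
                                  recomb_fraction = 0.3,
                                  distortion_weights = list(c(1, 1, 1),
                                                            c(1, 0.948, 0.444))),
                     seed = seed + 2L)
## per-copy effects: Indel I mostly late (50 DAG), SNP3 at both timepoints
effects <- matrix(c(0.235, 0.82, 0.235, 1.385), nrow = 2, byrow = TRUE,
                  dimnames = list(c("IndelI", "SNP3"), c("40DAG", "50DAG")))
pm <- phenotype_model(additive_effects = effects)

for (panel in list(list(gm = ril, tag = "ril"), list(gm = f2, tag = "f2"))) {
  geno <- t(panel$gm$geno); colnames(geno) <- loci$name
  ph <- simulate_phenotypes(geno, pm, seed = seed + 3L)
  utils::write.table(ph, file.path(out, sprintf("pheno_%s.tsv", panel$tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(line_id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(gdf, file.path(out, sprintf("geno_%s.tsv", panel$tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d lines genotyped at %s; phenotypes at %s\n", panel$tag,
              nrow(geno), paste(loci$name, collapse = ", "),
              paste(pm$timepoints, collapse = ", ")))
}
cat("stage 1 outputs under", out, "\n")
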