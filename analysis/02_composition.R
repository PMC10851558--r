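#!/usr/bin/env Rscript

## Stage 2: composition statistics. Per-genome gene tables, sliding-window
## %GC profiles (1 kb window, 200 bp step), pooled and per-genome PCG %GC
## with the 1%-bin histogram, signed intergenic distances, and the census
## of genes carrying A/T homopolymer runs of 10+ bases.

library(generosion)

state <- readRDS("scratch/01_state.rds")
out <- "results/composition"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
genomes <- state$red$genomes

for (g in genomes) {
  write_gene_table(gene_table(g), file.path(out, paste0(g$genome_id,
                                                        "_genes.tsv")))
  prof <- sliding_window_gc(g, window = 1000, step = 200)
  write_gc_profile(prof, file.path(out, paste0(g$genome_id,
                                               "_gc_profile.tsv")))
}

gcs <- pcg_gc_stats(genomes)
utils::write.table(gcs$per_genome, file.path(out, "pcg_gc_per_genome.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(bin = names(gcs$histogram),
                              count = as.integer(gcs$histogram)),
                   file.path(out, "pcg_gc_histogram.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

ig <- do.call(rbind, lapply(genomes, function(g)
  data.frame(genome_id = g$genome_id,
             mean_intergenic_bp = intergenic_stats(g, wrap = TRUE)$mean)))
utils::write.table(ig, file.path(out, "intergenic_means.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

census <- do.call(rbind, lapply(genomes, function(g) {
  res <- homopolymer_gene_census(g, bases = c("A", "T"), min_run = 10)
  data.frame(genome_id = g$genome_id, genes_with_runs = res$count)
}))
utils::write.table(census, file.path(out, "homopolymer_census.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

anc_gc <- gc_percent(state$anc$genome$sequence)
cat(sprintf("Pooled descendant PCG %%GC: %.2f (ancestor %.2f) over %d genes\n",
            gcs$pooled$mean, anc_gc, gcs$pooled$n))
cat(sprintf("Mean intergenic distance: %.1f bp (ancestral spacer %d bp)\n",
            mean(ig$mean_intergenic_bp), state$cfg$intergenic_mean))
cat("Genes with A/T runs >= 10:", paste(census$genes_with_runs,
                                        collapse = " "), "\n")
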