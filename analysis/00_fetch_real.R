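#!/usr/bin/env Rscript

## Optional stage 0: desk-scale metrics on the real endosymbiont records.
## Requires network access once, to populate the local genome cache
## (~/.cache/generosion); afterwards everything runs offline. Reports the
## annotation metrics of the Diuraphis noxia endosymbiont record, pooled
## protein-coding %GC over the study genomes, and the A/T homopolymer
## census.

library(generosion)

accessions <- c("NC_017256", "NC_011833", "NC_004545", "NC_008513",
                "NC_015662", "NZ_CP013259", "NZ_CP002701", "NC_004061",
                "NC_017259")
out <- "results/real_genomes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (acc in accessions) {
  if (is.na(locate_genome(acc, must_exist = FALSE))) {
    message("fetching ", acc)
    fetch_genome(acc)
  }
}

genomes <- lapply(accessions, function(a) read_genbank(locate_genome(a)))

tab <- do.call(rbind, lapply(genomes, function(g) {
  counts <- gene_kind_counts(g)
  pcg <- g$genes[g$genes$kind == "CDS" & !g$genes$pseudo, ]
  data.frame(genome_id = g$genome_id, size_bp = nchar(g$sequence),
             pcg = counts[["CDS"]], total_genes = counts[["total"]],
             avg_pcg_len = round(mean(pcg$end - pcg$start), 1),
             avg_intergenic = round(intergenic_stats(g)$mean, 1))
}))
utils::write.table(tab, file.path(out, "annotation_metrics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

gcs <- pcg_gc_stats(genomes)
utils::write.table(gcs$per_genome, file.path(out, "pcg_gc.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

bdn <- genomes[[which(vapply(genomes, function(g)
  grepl("CP013259", g$genome_id), logical(1)))]]
census <- homopolymer_gene_census(bdn, bases = c("A", "T"), min_run = 10)

print(tab)
cat(sprintf("Pooled PCG %%GC over %d genes: %.2f (SD %.2f)\n",
            gcs$pooled$n, gcs$pooled$mean, gcs$pooled$sd))
cat("BDn genes with A/T runs >= 10:", census$count, "\n")
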