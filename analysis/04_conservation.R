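#!/usr/bin/env Rscript

## Stage 4: the %GC-versus-identity framework and gene-content
## clustering. Pooled per-gene table, quadrant classification at the
## pooled means, the multiple regression of identity on %GC and relative
## length, correlations, and the shared-gene-content dendrogram.

library(generosion)

state <- readRDS("scratch/01_state.rds")
st3 <- readRDS("scratch/03_state.rds")
out <- "results/conservation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

per_gene <- do.call(rbind, lapply(names(state$red$genomes), function(gid) {
  a <- st3$assignments[[gid]]
  gt <- gene_table(state$red$genomes[[gid]])
  m <- match(gt$gene_id, a$query_gene)
  data.frame(genome_id = gid, gene_id = gt$gene_id, gc = gt$gc_percent,
             identity = a$identity[m],
             relative_length = a$relative_length[m])
}))
thr <- quadrant_thresholds(per_gene)
per_gene$quadrant <- quadrant_classify(per_gene$gc, per_gene$identity, thr)
utils::write.table(per_gene, file.path(out, "quadrants.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

## overlay: the simulator's protected category plays the role of an
## a-priori "expected to be conserved" gene set
protected <- names(which(state$red$truth$protected))
per_gene$anc_id <- sub("^D[0-9]+_", "", sub("_(f[12]|d2)$", "",
                                            per_gene$gene_id))
prot_counts <- quadrant_summary(
  transform(per_gene, gene_id = anc_id), protected)

fit <- fit_identity_model(per_gene)
corr <- gc_identity_correlation(per_gene)
jsonlite::write_json(list(
  thresholds = unclass(thr),
  quadrant_counts = as.list(quadrant_summary(per_gene)),
  protected_category_counts = as.list(prot_counts),
  regression = list(intercept = fit$intercept, coef_gc = fit$coef_gc,
                    coef_len = fit$coef_len,
                    standardized_coef_gc = fit$standardized_coef_gc,
                    standardized_coef_len = fit$standardized_coef_len,
                    r_squared = fit$r_squared, n = fit$n),
  pearson_r = corr$pearson$estimate,
  spearman_rho = corr$spearman$estimate),
  file.path(out, "conservation_summary.json"), auto_unbox = TRUE,
  digits = NA)

dn <- hierarchical_cluster(spearman_distance(presence_matrix(st3$array)))
write_newick(dn, file.path(out, "gene_content_dendrogram.nwk"))

cat(sprintf("Thresholds: %%GC %.2f, identity %.2f\n", thr$gc_mean,
            thr$identity_mean))
cat("Quadrant counts:",
    paste(names(quadrant_summary(per_gene)),
          quadrant_summary(per_gene), collapse = ", "), "\n")
cat(sprintf("Protected-category overlay: Q3 holds %d of %d classified\n",
            prot_counts[["Q3"]], sum(prot_counts)))
cat(sprintf("identity ~ %.2f + %.2f*gc + %.3f*rel_len (R^2 %.2f, r %.2f)\n",
            fit$intercept, fit$coef_gc, fit$coef_len, fit$r_squared,
            corr$pearson$estimate))
cat("Dendrogram:", dn$newick, "\n")
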