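#!/usr/bin/env Rscript

## Stage 5: within-host strain mixtures. Five aphid populations are
## simulated over the first descendant genome: each carries the resident
## strain plus a minor strain at 30%, with population-specific and shared
## variant sites drawn from two ancestral pools. Variants are called at
## the 100x / Q20 / 20% thresholds, classified as variable (20-80%),
## intersected across populations, effect-annotated and overlaid on the
## conservation quadrants.

library(generosion)

state <- readRDS("scratch/01_state.rds")
out <- "results/variants"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
g <- state$red$genomes[[1]]
seed <- state$cfg$seed

set.seed(seed + 500L)
L <- nchar(g$sequence)
pick_alt <- function(pos) {
  ref <- substring(g$sequence, pos + 1, pos + 1)
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
}
## two ancestral variant pools; each population draws a subset of pool
## sites plus a few private ones, so some sites recur across populations
pool <- sort(sample.int(L, 60) - 1L)
pool_alt <- pick_alt(pool)
pops <- paste0("POP", 1:5)
site_sets <- list()
for (p in pops) {
  take <- sort(sample(seq_along(pool), 25))
  priv <- sort(sample(setdiff(seq_len(L) - 1L, pool), 5))
  vars <- rbind(data.frame(position = pool[take], alt = pool_alt[take]),
                data.frame(position = priv, alt = pick_alt(priv)))
  vars <- vars[order(vars$position), ]
  strains <- list(list(variants = NULL, frequency = 0.7),
                  list(variants = vars, frequency = 0.3))
  pp <- simulate_pileup(g, strains, depth = 1000, error_rate = 0.001,
                        seed = seed + 600L + match(p, pops))
  called <- call_variants(pp$pileup, population = p)
  called <- classify_variable_sites(called)
  called <- annotate_effect(called, g)
  site_sets[[p]] <- called
}
all_sites <- do.call(rbind, site_sets)
utils::write.table(all_sites, file.path(out, "variant_sites.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

venn <- shared_variants(site_sets)
jsonlite::write_json(venn, file.path(out, "venn.json"), auto_unbox = TRUE,
                     digits = NA)

## overlay on the conservation quadrants of this genome
quad <- utils::read.table("results/conservation/quadrants.tsv",
                          header = TRUE, sep = "\t")
quad <- quad[quad$genome_id == g$genome_id, ]
qmap <- stats::setNames(quad$quadrant, quad$gene_id)
snp_q <- snp_quadrant_distribution(all_sites, qmap)
effects <- table(all_sites$effect)
jsonlite::write_json(list(effect_counts = as.list(effects),
                          snp_quadrants = as.list(snp_q)),
                     file.path(out, "effects.json"), auto_unbox = TRUE,
                     digits = NA)

cat("Variants called per population:",
    paste(names(site_sets), vapply(site_sets, nrow, 0L)), "\n")
cat("Union", venn$n_union, "sites;", venn$n_shared,
    "shared by at least two populations\n")
cat("Effects:", paste(names(effects), effects, collapse = ", "), "\n")
cat("Genic SNPs by quadrant:",
    paste(names(snp_q), snp_q, collapse = ", "), "\n")
cat("Variable (20-80%) sites:", sum(all_sites$variable), "of",
    nrow(all_sites), "\n")
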