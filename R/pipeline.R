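## End-to-end orchestration: simulated genomes -> gene tables -> homology
## -> gene array -> pan/core -> quadrants/regression -> clustering ->
## variants -> expression, with every report written under one output
## directory.

#' Run the full comparative pipeline on a simulated genome set
#'
#' Drives every stage of the package from one seeded configuration and
#' writes the standard report bundle: per-genome gene tables, homolog
#' assignments, the gene array TSV, pan/core JSON, the classified
#' quadrant table, the regression fit JSON, the gene-content dendrogram
#' (Newick), a strain-mixture variant report and an expression report.
#' The echoed configuration (with its MD5 hash and package version) makes
#' reruns reproducible: the same seed yields the same bundle.
#'
#' @param config List with any of the fields of [sim_config()] plus
#'   `out_dir` (required), `strain_frequencies` (default `c(0.7, 0.3)`),
#'   `n_planted_variants` (default 40), `pileup_depth` (default 1000).
#' @return Invisible list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_fields <- intersect(names(config), names(formals(sim_config)))
  cfg <- do.call(sim_config, config[cfg_fields])
  strain_freq <- config$strain_frequencies %||% c(0.7, 0.3)
  n_var <- config$n_planted_variants %||% 40L
  depth <- config$pileup_depth %||% 1000

  ## provenance: echo the configuration and hash it
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(c(unclass(cfg),
                         list(strain_frequencies = strain_freq,
                              n_planted_variants = n_var,
                              pileup_depth = depth)),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               package_version = as.character(utils::packageVersion(
                 "generosion")))

  ## 1. simulate
  anc <- generate_ancestor(cfg)
  red <- simulate_reduction(anc, cfg)
  genomes <- red$genomes

  ## 2. gene tables + composition
  for (g in genomes)
    write_gene_table(gene_table(g),
                     file.path(out, paste0(g$genome_id, "_genes.tsv")))
  gcs <- pcg_gc_stats(genomes)

  ## 3. homology against the ancestor proteome
  proteomes <- lapply(genomes, function(g) extract_proteome(g)$proteome)
  assignments <- lapply(names(genomes), function(gid)
    reciprocal_best_hits(proteomes[[gid]], anc$proteome))
  names(assignments) <- names(genomes)
  for (gid in names(assignments))
    write_assignments(cbind(query_genome = gid, assignments[[gid]]),
                      file.path(out, paste0(gid, "_homologs.tsv")))

  ## 4. gene array and derivatives
  arr <- build_array(genomes, assignments, proteomes)
  write_array_tsv(arr, file.path(out, "gene_array.tsv"))
  pc <- pan_core(arr)
  blocks <- syntenic_blocks(arr, anc$genome$genes$gene_id)
  devs <- strand_deviations(arr)
  splits <- detect_splits(arr, assignments)
  jsonlite::write_json(list(pan = as.list(pc$pan), core = as.list(pc$core),
                            syntenic_blocks = blocks$count,
                            provenance = prov),
                       file.path(out, "pan_core.json"), auto_unbox = TRUE,
                       digits = NA)

  ## 5. quadrants + regression over the pooled per-gene table
  per_gene <- do.call(rbind, lapply(names(genomes), function(gid) {
    a <- assignments[[gid]]
    gt <- gcs$per_gene[gcs$per_gene$genome_id == gid, ]
    m <- match(gt$gene_id, a$query_gene)
    data.frame(genome_id = gid, gene_id = gt$gene_id, gc = gt$gc,
               identity = a$identity[m],
               relative_length = a$relative_length[m])
  }))
  thr <- quadrant_thresholds(per_gene)
  per_gene$quadrant <- quadrant_classify(per_gene$gc, per_gene$identity, thr)
  utils::write.table(per_gene, file.path(out, "quadrants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fit <- fit_identity_model(per_gene)
  corr <- gc_identity_correlation(per_gene)
  jsonlite::write_json(list(
    intercept = fit$intercept, coef_gc = fit$coef_gc,
    coef_len = fit$coef_len,
    standardized_coef_gc = fit$standardized_coef_gc,
    standardized_coef_len = fit$standardized_coef_len,
    r_squared = fit$r_squared, n = fit$n,
    pearson_r = corr$pearson$estimate, provenance = prov),
    file.path(out, "regression.json"), auto_unbox = TRUE, digits = NA)

  ## 6. gene-content clustering
  dendro <- tryCatch(
    hierarchical_cluster(spearman_distance(presence_matrix(arr))),
    error = function(e) NULL)   # degenerate content (no variation)
  if (!is.null(dendro)) write_newick(dendro, file.path(out, "dendrogram.nwk"))

  ## 7. strain-mixture variants on the first descendant
  g1 <- genomes[[1]]
  set.seed(cfg$seed + 2000L)
  L <- nchar(g1$sequence)
  vpos <- sort(sample.int(L, n_var) - 1L)
  refb <- substring(g1$sequence, vpos + 1L, vpos + 1L)
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  strains <- list(list(variants = NULL, frequency = strain_freq[1]),
                  list(variants = data.frame(position = vpos, alt = altb),
                       frequency = strain_freq[2]))
  pile <- simulate_pileup(g1, strains, depth = depth, seed = cfg$seed + 3L)
  sites <- call_variants(pile$pileup, population = g1$genome_id)
  sites <- classify_variable_sites(sites)
  sites <- annotate_effect(sites, g1)
  qmap <- with(per_gene[per_gene$genome_id == g1$genome_id, ],
               stats::setNames(quadrant, gene_id))
  utils::write.table(sites, file.path(out, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  snp_q <- snp_quadrant_distribution(sites, qmap)

  ## 8. expression
  expr <- simulate_counts(g1$genes$gene_id, seed = cfg$seed + 4L)
  lc <- log_cpm(expr$table)
  tiers <- tier_classify(rowMeans(lc))
  names(tiers) <- rownames(lc)
  ex <- ex90(rowSums(expr$table$counts))
  jsonlite::write_json(list(
    ex90 = ex, tier_counts = as.list(table(tiers)),
    snp_quadrants = as.list(snp_q), provenance = prov),
    file.path(out, "expression.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(config = cfg, ancestor = anc, genomes = genomes,
                 truth = red$truth, gc_stats = gcs,
                 assignments = assignments, array = arr, pan_core = pc,
                 blocks = blocks, deviations = devs, splits = splits,
                 per_gene = per_gene, thresholds = thr, fit = fit,
                 correlation = corr, dendrogram = dendro,
                 variant_sites = sites, variant_truth = pile$truth,
                 snp_quadrants = snp_q, expression = expr,
                 tiers = tiers, ex90 = ex, provenance = prov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
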