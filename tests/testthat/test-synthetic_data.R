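test_that("configuration validates probabilities and rates", {
  expect_s3_class(sim_config(), "SimulationConfig")
  expect_error(sim_config(at_bias = 1.2), "probabilities")
  expect_error(sim_config(erosion_mean = -1), "rates")
})

test_that("the ancestor is deterministic, ORF-valid and on-target GC", {
  cfg <- sim_config(seed = 1, n_ancestor_genes = 60,
                    gene_length_mean = 450, gene_length_sd = 90)
  a1 <- generate_ancestor(cfg)
  a2 <- generate_ancestor(cfg)
  expect_identical(a1$genome$sequence, a2$genome$sequence)
  expect_identical(a1$genome$genes, a2$genome$genes)
  expect_equal(nrow(a1$genome$genes), 60L)
  expect_equal(gc_percent(a1$genome$sequence), 50, tolerance = 0.02)
  ## every gene translates without internal stops
  prot <- extract_proteome(a1$genome)
  expect_length(prot$split_candidates, 0L)
  seqs <- gene_sequence(a1$genome)
  expect_true(all(substr(seqs, 1, 3) == "ATG"))
  expect_true(all(substring(seqs, nchar(seqs) - 2) == "TAA"))
  ## a low-GC ancestor hits its target too
  cfg2 <- sim_config(seed = 2, n_ancestor_genes = 40, ancestor_gc = 30,
                     gene_length_mean = 450, gene_length_sd = 90)
  expect_equal(gc_percent(generate_ancestor(cfg2)$genome$sequence), 30,
               tolerance = 0.02)
})

test_that("zero-rate reduction reproduces the ancestor everywhere", {
  cfg <- sim_config(seed = 4, n_descendants = 2, n_ancestor_genes = 25,
                    gene_length_mean = 300, gene_length_sd = 50,
                    erosion_mean = 0, loss_max = 0, split_prob = 0,
                    dup_prob = 0, inversion_rate = 0,
                    strand_flip_prob = 0, intergenic_decay = 0)
  anc <- generate_ancestor(cfg)
  red <- simulate_reduction(anc, cfg)
  for (g in red$genomes) {
    expect_equal(nrow(g$genes), 25L)
    expect_equal(unname(gene_sequence(g)),
                 unname(gene_sequence(anc$genome)))
    expect_equal(g$genes$strand, anc$genome$genes$strand)
  }
  tpc <- truth_pan_core(red$truth)
  expect_equal(tpc$pan, 25L)
  expect_equal(tpc$core, 25L)
  pg <- red$truth$per_descendant[[1]]$per_gene
  expect_true(all(pg$identity == 100))
  expect_true(all(pg$subs == 0))
})

test_that("total loss leaves exactly the protected set", {
  cfg <- sim_config(seed = 6, n_descendants = 2, n_ancestor_genes = 30,
                    gene_length_mean = 300, gene_length_sd = 50,
                    loss_max = 1, loss_midpoint_gc = 1000, loss_scale = 1,
                    protected_weight = 0, split_prob = 0, dup_prob = 0,
                    inversion_rate = 0, strand_flip_prob = 0)
  anc <- generate_ancestor(cfg)
  red <- simulate_reduction(anc, cfg)
  protected <- names(which(red$truth$protected))
  for (d in names(red$genomes)) {
    kept <- sub("^D[0-9]+_", "", red$genomes[[d]]$genes$gene_id)
    expect_setequal(kept, protected)
    expect_setequal(red$truth$per_descendant[[d]]$lost,
                    setdiff(anc$genome$genes$gene_id, protected))
  }
})

test_that("the truth ledger reconciles with the emitted annotations", {
  sim <- small_simulation()
  for (d in names(sim$red$genomes)) {
    truth <- sim$red$truth$per_descendant[[d]]
    ids <- sim$red$genomes[[d]]$genes$gene_id
    ## lost genes are absent
    expect_false(any(paste0(d, "_", truth$lost, recycle0 = TRUE) %in% ids))
    ## split fragments and duplicates are present
    expect_true(all(unlist(truth$splits) %in% ids))
    expect_true(all(paste0(d, "_", truth$duplicated, "_d2",
                           recycle0 = TRUE) %in% ids))
    ## descendants erode toward AT
    pg <- truth$per_gene
    expect_lt(mean(pg$gc), 50)
    expect_true(all(pg$identity <= 100))
  }
})

test_that("erosion couples substitution load to %GC loss", {
  sim <- small_simulation()
  pg <- do.call(rbind, lapply(sim$red$truth$per_descendant,
                              `[[`, "per_gene"))
  ## more substitutions, lower GC and lower identity
  expect_lt(cor(pg$subs, pg$gc), 0)
  expect_lt(cor(pg$subs, pg$identity), -0.9)
})

test_that("pileup simulation is seed-stable and error-free at zero error", {
  cfg <- sim_config(seed = 8, n_descendants = 1, n_ancestor_genes = 10,
                    gene_length_mean = 300, gene_length_sd = 30)
  g <- generate_ancestor(cfg)$genome
  one <- list(list(variants = NULL, frequency = 1))
  pp <- simulate_pileup(g, one, depth = 200, error_rate = 0, seed = 9)
  counts <- as.matrix(pp$pileup[, c("A", "C", "G", "T")])
  nonref <- sum(counts) - sum(counts[cbind(seq_len(nrow(counts)),
                                           match(pp$pileup$ref,
                                                 colnames(counts)))])
  expect_equal(nonref, 0L)
  pp2 <- simulate_pileup(g, one, depth = 200, error_rate = 0, seed = 9)
  expect_identical(pp$pileup, pp2$pileup)
  expect_error(simulate_pileup(g, list(list(variants = NULL,
                                            frequency = 0.6))),
               "sum to 1")
  bad <- list(list(variants = data.frame(position = c(5, 5),
                                         alt = c("A", "C")),
                   frequency = 1))
  expect_error(simulate_pileup(g, bad), "conflicting")
})

test_that("expression simulation hits its planted tiers", {
  ids <- sprintf("g%03d", 1:200)
  sim <- simulate_counts(ids, dispersion = 0.001, seed = 13)
  lc <- rowMeans(log_cpm(sim$table))
  ## low dispersion, large library: logCPM close to the planted mean
  expect_gte(mean(abs(lc - sim$truth$planted_logcpm) < 0.2), 0.95)
  tiers <- tier_classify(lc)
  expect_gte(mean(tiers == sim$truth$tier), 0.95)
  ## degenerate fractions: everything low
  sim2 <- simulate_counts(ids, tier_fractions = c(low = 1, mid = 0,
                                                  high = 0), seed = 13)
  expect_true(all(tier_classify(rowMeans(log_cpm(sim2$table))) == "low"))
  sim3 <- simulate_counts(ids, dispersion = 0.001, seed = 13)
  expect_identical(sim$table$counts, sim3$table$counts)
})

test_that("identity-table generator plants a recoverable slope", {
  sim <- simulate_identity_table(n = 300, seed = 15)
  fit <- fit_identity_model(sim$table)
  ci <- fit$conf_int["gc", ]
  expect_gt(sim$truth$slope, ci[1])
  expect_lt(sim$truth$slope, ci[2])
})

test_that("planted synteny breaks create exactly k+1 blocks", {
  refs <- sprintf("r%03d", 1:60)
  rows <- data.frame(row_index = seq_along(refs), ref_gene = refs,
                     name = "", kind = "CDS", n_present = 1L,
                     direction_change = FALSE)
  arr <- toy_array(rows, data.frame(row_index = integer(0),
                                    genome_id = character(0),
                                    gene_id = character(0),
                                    strand = character(0),
                                    pos_in_genome = integer(0)), "A")
  expect_equal(syntenic_blocks(arr, refs)$count, 1L)
  for (k in c(1L, 2L, 4L)) {
    shuffled <- plant_synteny_breaks(refs, k)
    expect_equal(syntenic_blocks(arr, shuffled)$count, k + 1L)
  }
  expect_error(plant_synteny_breaks(refs, 30), "too many")
})
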