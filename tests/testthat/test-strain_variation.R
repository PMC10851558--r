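mk_pileup <- function(position, ref, alt, depth, alt_count, qual) {
  d <- data.frame(position = position, ref = ref, A = 0L, C = 0L, G = 0L,
                  T = 0L, ins = 0L, del = 0L, mean_qual = qual)
  alt <- rep(alt, length.out = nrow(d))
  ref <- rep(ref, length.out = nrow(d))
  depth <- rep(depth, length.out = nrow(d))
  alt_count <- rep(alt_count, length.out = nrow(d))
  for (i in seq_len(nrow(d))) {
    d[i, ref[i]] <- depth[i] - alt_count[i]
    d[i, alt[i]] <- alt_count[i]
  }
  d
}

test_that("variant filters apply the coverage/quality/frequency gates", {
  p <- mk_pileup(position = c(100, 200, 300),
                 ref = c("A", "A", "A"), alt = c("G", "G", "G"),
                 depth = c(150, 80, 200), alt_count = c(45, 40, 30),
                 qual = c(30, 30, 30))
  v <- call_variants(p)
  expect_equal(v$position, 100)       # 80x fails depth, 15% fails frequency
  expect_equal(v$frequency, 0.30)
  ## thresholds are inclusive
  p2 <- mk_pileup(100, "A", "G", 100, 20, 20)
  expect_equal(nrow(call_variants(p2)), 1L)
  ## quality gate
  p3 <- mk_pileup(100, "A", "G", 150, 45, 19.9)
  expect_equal(nrow(call_variants(p3)), 0L)
})

test_that("multi-allelic sites emit one record per passing allele", {
  d <- data.frame(position = 5, ref = "A", A = 100L, C = 60L, G = 40L,
                  T = 0L, ins = 0L, del = 0L, mean_qual = 30)
  v <- call_variants(d)
  expect_equal(nrow(v), 2L)
  expect_setequal(v$alt_allele, c("C", "G"))
  expect_equal(sum(v$frequency), 0.5)
})

test_that("filtering is monotone in all three thresholds", {
  set.seed(51)
  n <- 60
  depth <- sample(50:400, n, TRUE)
  altc <- rbinom(n, depth, runif(n, 0.05, 0.6))
  p <- mk_pileup(seq_len(n), sample(c("A", "C", "G", "T"), n, TRUE),
                 "G", depth, pmin(altc, depth), runif(n, 15, 35))
  p$G <- ifelse(p$ref == "G", p$G, p$G)   # ref==alt rows simply yield no alt
  base <- nrow(call_variants(p, 50, 10, 0.05))
  for (th in list(c(100, 10, 0.05), c(50, 20, 0.05), c(50, 10, 0.2))) {
    expect_lte(nrow(call_variants(p, th[1], th[2], th[3])), base)
  }
})

test_that("variable-site window is inclusive at both ends", {
  s <- data.frame(frequency = c(0.5, 0.95, 0.2, 0.8, 0.19))
  out <- classify_variable_sites(s)
  expect_equal(out$variable, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("shared variants follow set algebra", {
  mk <- function(pos) data.frame(population = "x", position = pos,
                                 ref_allele = "A", alt_allele = "G")
  res <- shared_variants(list(P1 = mk(c(1, 2)), P2 = mk(c(2, 3))))
  expect_equal(res$n_union, 3L)
  expect_equal(res$n_shared, 1L)
  expect_equal(res$subset_counts[["P1&P2"]], 1L)
  res2 <- shared_variants(list(P1 = mk(1:2), P2 = mk(3:4)))
  expect_equal(res2$n_shared, 0L)
  ## random site sets against a direct set-algebra oracle
  set.seed(52)
  pools <- lapply(1:5, function(i) mk(sample(1:40, sample(5:15, 1))))
  names(pools) <- paste0("P", 1:5)
  res3 <- shared_variants(pools)
  keys <- lapply(pools, function(p) p$position)
  uni <- unique(unlist(keys))
  shared_oracle <- sum(vapply(uni, function(k)
    sum(vapply(keys, function(x) k %in% x, logical(1))) >= 2, logical(1)))
  expect_equal(res3$n_shared, shared_oracle)
  expect_equal(sum(unlist(res3$subset_counts)), length(uni))
})

test_that("coding effects come from strand-aware codon re-translation", {
  ## gene on + strand: ATG GCT AAA TAA ; gene on - strand: ATG GCT TAA
  g <- toy_genome("V", data.frame(
    name = c("plus", "minus"),
    seq = c("ATGGCTAAATAA", "ATGGCTTAA"),
    strand = c("+", "-")), spacer = 10L)
  st <- g$genes$start
  sites <- data.frame(
    population = "p",
    ## GCT -> GCC (synonymous), GCT -> GTT (missense), AAA -> TAA (stop)
    position = c(st[1] + 5, st[1] + 4, st[1] + 6),
    ref_allele = c("T", "C", "A"),
    alt_allele = c("C", "T", "T"),
    depth = 100, alt_count = 50, frequency = 0.5,
    mean_base_quality = 30)
  out <- annotate_effect(sites, g)
  expect_equal(out$effect, c("synonymous", "missense", "stop_gained"))
  expect_equal(out$aa_change[2], "A2V")
  ## minus strand: genomic base maps through the reverse complement;
  ## gene "minus" occupies [st2, st2+9); genomic TTA AGC CAT
  st2 <- g$genes$start[2]
  ## genomic position of codon2 base3 (GCT third base, genomic index st2+3)
  s2 <- data.frame(population = "p", position = st2 + 3,
                   ref_allele = "A", alt_allele = "G",
                   depth = 100, alt_count = 50, frequency = 0.5,
                   mean_base_quality = 30)
  out2 <- annotate_effect(s2, g)
  expect_equal(out2$gene_id, "V_minus")
  expect_equal(out2$effect, "synonymous")   # GCT -> GCC, still Ala
  ## indels and intergenic positions
  s3 <- data.frame(population = "p", position = c(st[1] + 4, 0),
                   ref_allele = c("C", "T"), alt_allele = c("del", "G"),
                   depth = 100, alt_count = 50, frequency = 0.5,
                   mean_base_quality = 30)
  out3 <- annotate_effect(s3, g)
  expect_equal(out3$effect, c("frameshift", "intergenic"))
  expect_error(annotate_effect(
    data.frame(position = nchar(g$sequence) + 5, ref_allele = "A",
               alt_allele = "G"), g), "beyond")
})

test_that("effect annotation agrees with whole-protein re-translation", {
  set.seed(53)
  cfg <- sim_config(seed = 53, n_descendants = 1, n_ancestor_genes = 10,
                    gene_length_mean = 300, gene_length_sd = 30)
  g <- generate_ancestor(cfg)$genome
  prot0 <- extract_proteome(g)$proteome
  gn <- g$genes
  for (k in 1:100) {
    i <- sample(nrow(gn), 1)
    pos <- sample(seq(gn$start[i], gn$end[i] - 1L), 1)
    ref <- substring(g$sequence, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    site <- data.frame(population = "p", position = pos, ref_allele = ref,
                       alt_allele = alt, depth = 100, alt_count = 50,
                       frequency = 0.5, mean_base_quality = 30)
    eff <- annotate_effect(site, g)$effect
    ## oracle: mutate the genome, re-translate the whole CDS
    mut <- g
    substr(mut$sequence, pos + 1, pos + 1) <- alt
    nt <- gene_sequence(mut, gn$gene_id[i])
    aa_new <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(nt), genetic.code =
        Biostrings::getGeneticCode("11"))))
    aa_new <- sub("\\*$", "", aa_new)
    aa_old <- prot0[[gn$gene_id[i]]]
    oracle <- if (grepl("\\*", aa_new)) "stop_gained"
              else if (aa_new == aa_old) "synonymous" else "missense"
    expect_equal(eff, oracle, info = paste(gn$gene_id[i], pos, ref, alt))
  }
})

test_that("quadrant distribution covers genic sites only", {
  sites <- data.frame(gene_id = c("g1", "g2", "g3", "g4", NA),
                      effect = c("missense", "synonymous", "frameshift",
                                 "missense", "intergenic"))
  qmap <- c(g1 = "Q1", g2 = "Q2", g3 = "Q3", g4 = "Q4")
  out <- snp_quadrant_distribution(sites, qmap)
  expect_equal(unname(out[c("Q1", "Q2", "Q3", "Q4")]), rep(1L, 4))
  expect_equal(unname(out["unclassified"]), 0L)
  allint <- data.frame(gene_id = NA_character_, effect = "intergenic")
  expect_equal(sum(snp_quadrant_distribution(allint, qmap)), 0L)
  noq <- data.frame(gene_id = "gX", effect = "missense")
  expect_equal(unname(snp_quadrant_distribution(noq, qmap)["unclassified"]),
               1L)
})

test_that("pileup reader flags malformed rows with line numbers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tref\tA\tC\tG\tT\tins\tdel\tmean_qual",
               "1\tA\t10\t0\t0\t0\t0\t0\t30",
               "2\tC\txx\t0\t0\t0\t0\t0\t30"), tf)
  expect_error(read_pileup(tf), "line 3")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tref\tA", "1\tA\t10"), tf2)
  expect_error(read_pileup(tf2), "missing columns")
})

test_that("VCF ingestion yields the same site table shape", {
  skip_if_not_installed("vcfR")
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr\t11\t.\tA\tG\t40\tPASS\t.\tAD:DP\t70,30:100",
    "chr\t21\t.\tC\tT,G\t35\tPASS\t.\tAD:DP\t50,30,20:100"), tf)
  sites <- read_vcf_sites(tf, population = "P")
  expect_equal(nrow(sites), 3L)
  expect_equal(sites$position, c(10, 20, 20))    # 0-based
  expect_equal(sites$frequency, c(0.3, 0.3, 0.2))
  expect_equal(sites$depth, c(100, 100, 100))
})

test_that("planted mixture frequencies are recovered within binomial error", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_descendants = 1, n_ancestor_genes = 10,
                    gene_length_mean = 300, gene_length_sd = 30)
  g <- generate_ancestor(cfg)$genome
  vpos <- sort(sample(nchar(g$sequence), 30) - 1L)
  refb <- substring(g$sequence, vpos + 1, vpos + 1)
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  strains <- list(list(variants = NULL, frequency = 0.7),
                  list(variants = data.frame(position = vpos, alt = altb),
                       frequency = 0.3))
  pp <- simulate_pileup(g, strains, depth = 1000, error_rate = 0,
                        seed = 11)
  v <- call_variants(pp$pileup)
  v <- classify_variable_sites(v)
  m <- match(pp$truth$position, v$position)
  expect_false(anyNA(m))
  err <- abs(v$frequency[m] - pp$truth$planted_freq)
  bound <- 3 * sqrt(0.3 * 0.7 / v$depth[m])
  expect_lt(mean(err), mean(bound))   # unbiased within binomial noise
  expect_true(all(v$variable[m]))
})
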