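test_that("name-anchored array reproduces hand-constructed presence", {
  set.seed(21)
  seqs <- setNames(replicate(3, random_orf(30)), c("a", "b", "c"))
  mk <- function(id, names) toy_genome(id, data.frame(name = names,
                                                      seq = seqs[names]))
  g1 <- mk("G1", c("a", "b", "c"))
  g2 <- mk("G2", c("a", "c"))
  g3 <- mk("G3", c("a", "b", "c"))
  arr <- build_array(list(g1, g2, g3))
  expect_equal(nrow(arr$rows), 3L)
  pm <- presence_matrix(arr)
  expect_equal(unname(pm), rbind(c(1, 1, 1), c(1, 0, 1), c(1, 1, 1)))
  expect_true(all(check_array_order(arr, list(g1, g2, g3))))
  ## row sums feed pan/core presence counts
  expect_equal(unname(rowSums(pm)), arr$rows$n_present)
  pc <- pan_core(arr)
  expect_equal(unname(pc$pan["total"]), 3L)
  expect_equal(unname(pc$core["total"]), 2L)
})

test_that("a single genome maps to one row per gene", {
  set.seed(22)
  g <- toy_genome("S", data.frame(name = c("x", "y", "z"),
                                  seq = replicate(3, random_orf(25))))
  arr <- build_array(list(g))
  expect_equal(nrow(arr$rows), 3L)
  expect_equal(arr$cells$gene_id, g$genes$gene_id)
})

test_that("identical genomes give pan equal to core", {
  set.seed(23)
  genes <- data.frame(name = c("u", "v"), seq = replicate(2, random_orf(20)))
  g1 <- toy_genome("I1", genes); g2 <- toy_genome("I2", genes)
  pc <- pan_core(build_array(list(g1, g2)))
  expect_equal(pc$pan, pc$core)
})

test_that("genomes without shared anchors are rejected", {
  set.seed(24)
  g1 <- toy_genome("N1", data.frame(name = "only1", seq = random_orf(20)))
  g2 <- toy_genome("N2", data.frame(name = "only2", seq = random_orf(20)))
  expect_error(build_array(list(g1, g2)), "no anchors.*N1.*N2")
})

test_that("rows compacted by shared reference identity merge in the pan", {
  rows <- data.frame(row_index = 1:3,
                     ref_gene = c("grpE", "grpE", NA),
                     name = c("grpE", "grpE", ""), kind = "CDS",
                     n_present = c(2L, 1L, 1L), direction_change = FALSE)
  cells <- data.frame(row_index = c(1L, 1L, 2L, 3L),
                      genome_id = c("A", "B", "A", "B"),
                      gene_id = c("a1", "b1", "a2", "b2"),
                      strand = "+", pos_in_genome = c(1L, 1L, 2L, 2L))
  pc <- pan_core(toy_array(rows, cells, c("A", "B")))
  expect_equal(unname(pc$pan["total"]), 2L)   # grpE counted once
  expect_equal(unname(pc$core["total"]), 1L)  # grpE unit covers both genomes
})

test_that("split fragments are detected by length-sum and adjacency", {
  rows <- data.frame(row_index = 1:4, ref_gene = c("R1", "R1", "R2", "R2"),
                     name = "", kind = "CDS", n_present = 1L,
                     direction_change = FALSE)
  cells <- data.frame(row_index = 1:4, genome_id = "X",
                      gene_id = c("f1", "f2", "p1", "p2"), strand = "+",
                      pos_in_genome = 1:4)
  arr <- toy_array(rows, cells, "X")
  asn <- list(X = data.frame(
    query_gene = c("f1", "f2", "p1", "p2"),
    ref_gene = c("R1", "R1", "R2", "R2"),
    relative_length = c(55, 45, 100, 100)))
  res <- detect_splits(arr, asn, length_tolerance = 0.15)
  expect_equal(nrow(res$splits), 1L)
  expect_equal(res$splits$ref_gene, "R1")
  expect_equal(res$splits$fragments, "f1;f2")
  ## the full-length adjacent paralogs (sum 200%) are not a split
  expect_false("R2" %in% res$splits$ref_gene)
})

test_that("no splits are reported in a clean genome", {
  sim <- small_simulation()
  clean <- names(Filter(function(d) length(d$splits) == 0,
                        sim$red$truth$per_descendant))
  if (length(clean)) {
    res <- detect_splits(sim$array, sim$assignments)
    expect_false(any(res$splits$genome_id %in% clean))
  }
  succeed()
})

test_that("strand deviations split into isolated flips and inversions", {
  rows <- data.frame(row_index = 1:8, ref_gene = NA, name = "",
                     kind = "CDS", n_present = 2L,
                     direction_change = FALSE)
  mkcells <- function(rowv, strandv, gid, posv = seq_along(rowv))
    data.frame(row_index = rowv, genome_id = gid,
               gene_id = paste0(gid, "_", seq_along(rowv)),
               strand = strandv, pos_in_genome = posv)
  base <- mkcells(1:8, rep("+", 8), "REF")
  ## G1: one isolated flip at row 2
  g1 <- mkcells(1:8, c("+", "-", rep("+", 6)), "G1")
  ## G2: rows 4..6 flipped and locally reversed (an inversion of size 3)
  g2 <- mkcells(c(1:3, 6, 5, 4, 7, 8),
                c("+", "+", "+", "-", "-", "-", "+", "+"), "G2")
  arr <- toy_array(rows, rbind(base, base, g1, g2),
                   c("REF", "REF2", "G1", "G2"))
  res <- strand_deviations(arr)
  expect_equal(nrow(res$direction_changes), 1L)
  expect_equal(res$direction_changes$genome_id, "G1")
  expect_equal(res$direction_changes$row_index, 2L)
  expect_equal(nrow(res$inversions), 1L)
  expect_equal(res$inversions$size, 3L)
  expect_equal(res$inversions$start_row, 4L)
  expect_equal(res$inversions$end_row, 6L)
  ## no flips at all: both reports empty
  quiet <- toy_array(rows, rbind(base, base), c("REF", "REF2"))
  res2 <- strand_deviations(quiet)
  expect_equal(nrow(res2$direction_changes), 0L)
  expect_equal(nrow(res2$inversions), 0L)
})

test_that("syntenic blocks follow consecutive reference indices", {
  mkrows <- function(refs) data.frame(
    row_index = seq_along(refs), ref_gene = refs, name = "", kind = "CDS",
    n_present = 1L, direction_change = FALSE)
  ref_order <- paste0("r", 1:10)
  ## indices 1,2,3,5,6 -> two blocks
  arr <- toy_array(mkrows(paste0("r", c(1, 2, 3, 5, 6))),
                   data.frame(row_index = integer(0),
                              genome_id = character(0),
                              gene_id = character(0), strand = character(0),
                              pos_in_genome = integer(0)), "A")
  res <- syntenic_blocks(arr, ref_order)
  expect_equal(res$count, 2L)
  expect_equal(res$blocks$size, c(3L, 2L))
  ## perfectly collinear -> one block
  res2 <- syntenic_blocks(toy_array(mkrows(paste0("r", 1:7)),
                                    arr$cells, "A"), ref_order)
  expect_equal(res2$count, 1L)
  ## descending indices -> one reversed block
  res3 <- syntenic_blocks(toy_array(mkrows(paste0("r", 3:1)),
                                    arr$cells, "A"), ref_order)
  expect_equal(res3$count, 1L)
  expect_equal(res3$blocks$orientation, "reversed")
  ## unassigned rows are skipped without breaking by default, break when
  ## skip_unassigned = FALSE
  refs <- c("r1", "r2", NA, "r3", "r4")
  res4 <- syntenic_blocks(toy_array(mkrows(refs), arr$cells, "A"), ref_order)
  expect_equal(res4$count, 1L)
  res5 <- syntenic_blocks(toy_array(mkrows(refs), arr$cells, "A"), ref_order,
                          skip_unassigned = FALSE)
  expect_equal(res5$count, 2L)
})

test_that("array TSV export keeps one labelled column per genome", {
  sim <- small_simulation()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_array_tsv(sim$array, tf)
  tab <- utils::read.table(tf, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(nrow(tab), nrow(sim$array$rows))
  expect_true(all(sim$array$genome_ids %in% names(tab)))
  ## cell syntax gene(strand)
  expect_match(tab[["D01"]][tab[["D01"]] != ""][1], "\\([+-]\\)")
})

test_that("pan is bounded below by core and above by nothing smaller", {
  sim <- small_simulation()
  pc <- pan_core(sim$array)
  expect_gte(pc$pan["total"], pc$core["total"])
  per_genome <- vapply(sim$red$genomes, function(g) nrow(g$genes),
                       integer(1))
  expect_lte(pc$core["total"], min(per_genome))
  ## on simulated data the array recovers the truth ledger exactly
  tpc <- truth_pan_core(sim$red$truth)
  expect_equal(unname(pc$pan["total"]), tpc$pan)
  expect_equal(unname(pc$core["total"]), tpc$core)
})
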