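## The synteny-ordered gene array: ordered rows of positional homologs
## across N genomes, and everything derived from it (pan/core genome,
## split genes, duplications, strand deviations and inversions, syntenic
## blocks, the binary presence/absence matrix).

#' Build a synteny-ordered gene array across genomes
#'
#' Rows are anchored on genes that share a gene name or a reciprocal
#' reference assignment across genomes. Each circular gene order is
#' rotated so that its first placed gene matches the earliest existing
#' row. Genes without an anchor are placed by interval interpolation
#' between their flanking anchors and merged into an existing row only if
#' their protein identity to a row member reaches `merge_threshold`
#' percent; otherwise they found a new row. A second gene of the same
#' genome hitting an occupied row (a duplicate or split fragment) founds
#' an adjacent row carrying the same identity, so that fragment and
#' duplicate rows sit next to their parent, as a manually curated array
#' would place them.
#'
#' @param genomes List of `GenomeRecord`s (named by genome id, or names
#'   are taken from the records).
#' @param assignments Named list (per genome) of homolog assignment
#'   tables from [reciprocal_best_hits()] against one shared reference;
#'   `NULL` to anchor by gene names only.
#' @param proteomes Named list (per genome) of proteomes (named amino-acid
#'   vectors), used only for the identity-merge of unanchored genes;
#'   `NULL` disables merging (every unanchored gene founds a row).
#' @param merge_threshold Percent identity required to merge an unanchored
#'   gene into an existing row (default 30, the twilight-zone floor).
#' @param matrix,gap_open,gap_extend Alignment parameters for the merge
#'   test.
#' @return An object of class `GeneArray`: list with `genome_ids`,
#'   `rows` (data.frame `row_index, ref_gene, name, kind, n_present,
#'   direction_change`) and `cells` (data.frame `row_index, genome_id,
#'   gene_id, strand, pos_in_genome`).
#' @export
build_array <- function(genomes, assignments = NULL, proteomes = NULL,
                        merge_threshold = 30, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (length(genomes) < 1L) stop("need at least one genome")
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- gids
  sub <- if (!is.null(proteomes) && is.character(matrix))
    substitution_matrix(matrix) else matrix

  ## per-genome gene info with anchor keys
  info <- lapply(gids, function(gid) {
    gn <- genomes[[gid]]$genes
    asn <- if (!is.null(assignments)) assignments[[gid]] else NULL
    key_ref <- rep(NA_character_, nrow(gn))
    best_ref <- rep(NA_character_, nrow(gn))
    if (!is.null(asn)) {
      m <- match(gn$gene_id, asn$query_gene)
      best_ref <- asn$ref_gene[m]
      key_ref <- ifelse(!is.na(m) & asn$reciprocal[m], asn$ref_gene[m],
                        NA_character_)
    }
    data.frame(gene_id = gn$gene_id, name = gn$name, kind = gn$kind,
               strand = gn$strand, key_ref = key_ref, best_ref = best_ref,
               stringsAsFactors = FALSE)
  })
  names(info) <- gids

  ## rows are kept as parallel vectors indexed by a stable creation id;
  ## `ord` holds creation ids in display order
  row_name <- character(0); row_ref <- character(0); row_kind <- character(0)
  ord <- integer(0)
  by_name <- new.env(parent = emptyenv())
  by_ref <- new.env(parent = emptyenv())
  occupied <- new.env(parent = emptyenv())   # "rowid|genome" -> TRUE
  cells <- list()

  lookup <- function(name, key_ref) {
    if (nzchar(name) && !is.null(by_name[[name]])) return(by_name[[name]])
    if (!is.na(key_ref) && !is.null(by_ref[[key_ref]])) return(by_ref[[key_ref]])
    NA_integer_
  }
  new_row <- function(name, ref, kind, after_pos) {
    id <- length(row_name) + 1L
    row_name[id] <<- if (is.na(name)) "" else name
    row_ref[id] <<- ref
    row_kind[id] <<- kind
    ord <<- append(ord, id, after = after_pos)
    if (nzchar(row_name[id]) && is.null(by_name[[row_name[id]]]))
      by_name[[row_name[id]]] <- id
    if (!is.na(ref) && is.null(by_ref[[ref]])) by_ref[[ref]] <- id
    id
  }
  place <- function(rowid, gid, gene_id, strand, pos) {
    cells[[length(cells) + 1L]] <<- list(rowid = rowid, genome_id = gid,
                                         gene_id = gene_id, strand = strand,
                                         pos_in_genome = pos)
    occupied[[paste0(rowid, "|", gid)]] <- TRUE
  }

  for (gi in seq_along(gids)) {
    gid <- gids[gi]
    gn <- info[[gid]]
    n <- nrow(gn)
    if (!n) next
    ## rotation: start at the gene matching the earliest existing row
    rot <- 0L
    if (gi > 1L && genomes[[gid]]$circular) {
      pos_of <- vapply(seq_len(n), function(i) {
        r <- lookup(gn$name[i], gn$key_ref[i])
        if (is.na(r)) NA_integer_ else match(r, ord)
      }, integer(1))
      if (all(is.na(pos_of)))
        stop("no anchors between genomes ", gids[1], " and ", gid)
      rot <- which.min(pos_of) - 1L
    }
    idx <- if (rot > 0L) c((rot + 1L):n, 1L:rot) else seq_len(n)
    gn <- gn[idx, , drop = FALSE]

    cursor <- 0L   # position in `ord` after which new rows are inserted
    for (i in seq_len(n)) {
      r <- lookup(gn$name[i], gn$key_ref[i])
      if (!is.na(r) && is.null(occupied[[paste0(r, "|", gid)]])) {
        place(r, gid, gn$gene_id[i], gn$strand[i], i)
        cursor <- match(r, ord)
        next
      }
      if (!is.na(r)) {
        ## duplicate/fragment: adjacent row with the same identity
        after <- max(match(r, ord), cursor)
        r2 <- new_row(gn$name[i], gn$best_ref[i], gn$kind[i], after)
        place(r2, gid, gn$gene_id[i], gn$strand[i], i)
        cursor <- match(r2, ord)
        next
      }
      ## unanchored: try identity merge into rows before the next anchor
      merged <- FALSE
      if (!is.null(proteomes) && gn$kind[i] == "CDS") {
        nxt <- length(ord) + 1L
        if (i < n) for (k in (i + 1L):n) {
          rk <- lookup(gn$name[k], gn$key_ref[k])
          if (!is.na(rk)) { nxt <- match(rk, ord); break }
        }
        q <- proteomes[[gid]][[gn$gene_id[i]]]
        if (!is.null(q) && nxt > cursor + 1L) {
          cand <- ord[seq(cursor + 1L, nxt - 1L)]
          cand <- cand[vapply(cand, function(cr)
            is.null(occupied[[paste0(cr, "|", gid)]]), logical(1))]
          best_id <- NA_integer_; best_pid <- -Inf
          for (cr in cand) {
            member <- Filter(function(cl) cl$rowid == cr, cells)[1]
            if (!length(member) || is.null(member[[1]])) next
            p <- proteomes[[member[[1]]$genome_id]][[member[[1]]$gene_id]]
            if (is.null(p)) next
            pid <- percent_identity(global_align(q, p, sub, gap_open,
                                                 gap_extend))
            if (pid > best_pid) { best_pid <- pid; best_id <- cr }
          }
          if (!is.na(best_id) && best_pid >= merge_threshold) {
            place(best_id, gid, gn$gene_id[i], gn$strand[i], i)
            cursor <- match(best_id, ord)
            merged <- TRUE
          }
        }
      }
      if (!merged) {
        r2 <- new_row(gn$name[i], gn$best_ref[i], gn$kind[i], cursor)
        place(r2, gid, gn$gene_id[i], gn$strand[i], i)
        cursor <- match(r2, ord)
      }
    }
  }

  cells_df <- do.call(rbind, lapply(cells, as.data.frame))
  cells_df$row_index <- match(cells_df$rowid, ord)
  cells_df <- cells_df[order(cells_df$row_index, cells_df$genome_id),
                       c("row_index", "genome_id", "gene_id", "strand",
                         "pos_in_genome")]
  rownames(cells_df) <- NULL

  ## row metadata: reference identity (reciprocal first, else any best
  ## hit of a member), majority kind, strand deviation flag
  Rn <- length(ord)
  meta <- data.frame(row_index = seq_len(Rn), ref_gene = NA_character_,
                     name = row_name[ord], kind = row_kind[ord],
                     n_present = 0L, direction_change = FALSE)
  sp <- split(cells_df, cells_df$row_index)
  for (nm in names(sp)) {
    d <- sp[[nm]]; ri <- as.integer(nm)
    meta$n_present[ri] <- length(unique(d$genome_id))
    refs <- unlist(lapply(seq_len(nrow(d)), function(j) {
      gi <- info[[d$genome_id[j]]]
      k <- match(d$gene_id[j], gi$gene_id)
      gi$key_ref[k]
    }))
    if (all(is.na(refs))) refs <- unlist(lapply(seq_len(nrow(d)), function(j) {
      gi <- info[[d$genome_id[j]]]
      gi$best_ref[match(d$gene_id[j], gi$gene_id)]
    }))
    refs <- refs[!is.na(refs)]
    if (length(refs))
      meta$ref_gene[ri] <- names(sort(table(refs), decreasing = TRUE))[1]
    strands <- d$strand
    maj <- names(sort(table(strands), decreasing = TRUE))[1]
    meta$direction_change[ri] <- any(strands != maj)
  }

  arr <- structure(list(genome_ids = gids, rows = meta, cells = cells_df),
                   class = "GeneArray")
  ## every genome pair must share at least one row
  pm <- presence_matrix(arr)
  if (length(gids) > 1L) for (i in seq_along(gids)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (!any(pm[, i] & pm[, j]))
        stop("no anchors between genomes ", gids[j], " and ", gids[i])
    }
  }
  arr
}

#' @export
print.GeneArray <- function(x, ...) {
  cat(sprintf("GeneArray: %d rows x %d genomes (%d cells)\n",
              nrow(x$rows), length(x$genome_ids), nrow(x$cells)))
  invisible(x)
}

#' Check the per-genome order-preservation invariant of a gene array
#'
#' Reading each genome's cells top-to-bottom must yield that genome's
#' genes in genomic order, up to one circular rotation. Inverted segments
#' (detected separately) legitimately violate this locally; builds without
#' inversions must pass.
#'
#' @param array A `GeneArray`.
#' @param genomes The list of `GenomeRecord`s the array was built from.
#' @return Named logical vector, one entry per genome.
#' @export
check_array_order <- function(array, genomes) {
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  out <- logical(length(gids)); names(out) <- gids
  for (gid in gids) {
    d <- array$cells[array$cells$genome_id == gid, ]
    d <- d[order(d$row_index, d$pos_in_genome), ]
    got <- d$gene_id
    want <- genomes[[match(gid, gids)]]$genes$gene_id
    ok <- FALSE
    if (length(got) == length(want)) {
      for (rot in seq_along(want) - 1L) {
        w <- if (rot > 0) c(want[(rot + 1):length(want)], want[1:rot])
             else want
        if (identical(got, w)) { ok <- TRUE; break }
      }
    }
    out[gid] <- ok
  }
  out
}

#' Pan and core genome from a gene array
#'
#' Rows sharing the same reference identity are compacted into one pan
#' unit (duplicate and split-fragment rows collapse onto their parent);
#' rows without a reference identity stand alone. A unit is core when its
#' member rows jointly cover every genome.
#'
#' @param array A `GeneArray`.
#' @return List with `pan` and `core` (named integer vectors per gene
#'   kind plus `total`) and `units` (data.frame mapping rows to units).
#' @export
pan_core <- function(array) {
  meta <- array$rows
  unit <- ifelse(is.na(meta$ref_gene),
                 paste0("row:", meta$row_index),
                 paste0("ref:", meta$ref_gene))
  pres <- presence_matrix(array)
  units <- data.frame(row_index = meta$row_index, unit = unit,
                      kind = meta$kind)
  u <- split(seq_len(nrow(meta)), unit)
  kind_of <- vapply(u, function(ix) meta$kind[ix[1]], character(1))
  core_of <- vapply(u, function(ix) {
    all(colSums(pres[ix, , drop = FALSE]) > 0)
  }, logical(1))
  count_by_kind <- function(kinds) {
    v <- vapply(GENE_KINDS, function(k) sum(kinds == k), integer(1))
    c(v, total = length(kinds))
  }
  list(pan = count_by_kind(kind_of),
       core = count_by_kind(kind_of[core_of]),
       units = units)
}

#' Detect split genes in a gene array
#'
#' A split is two or more genes of one genome, adjacent in that genome's
#' gene order (allowing `max_gap_rows` intervening genes), whose best
#' reference hit is
#' the same gene and whose summed amino-acid length is within
#' `1 +/- length_tolerance` of the reference length (summed relative
#' lengths within `100 * (1 +/- tol)`). Full-length adjacent paralogs fail
#' the length test and are reported as duplications instead by their
#' summed length near 200%.
#'
#' @param array A `GeneArray`.
#' @param assignments Named list (per genome) of assignment tables with
#'   `query_gene`, `ref_gene`, `relative_length`.
#' @param length_tolerance Fractional tolerance on the summed length
#'   (default 0.15).
#' @param max_gap_rows Intervening genes allowed between fragments
#'   (default 1).
#' @param internal_stop_candidates Optional character vector of gene ids
#'   flagged by [extract_proteome()]; passed through in the report.
#' @return List with `splits` (data.frame `genome_id, ref_gene,
#'   fragments, n_fragments, total_relative_length`) and
#'   `internal_stop_candidates`.
#' @export
detect_splits <- function(array, assignments, length_tolerance = 0.15,
                          max_gap_rows = 1L,
                          internal_stop_candidates = character(0)) {
  out <- list()
  for (gid in array$genome_ids) {
    asn <- assignments[[gid]]
    d <- array$cells[array$cells$genome_id == gid, ]
    d <- d[order(d$pos_in_genome), ]
    if (!nrow(d)) next
    m <- match(d$gene_id, asn$query_gene)
    d$ref <- asn$ref_gene[m]
    d$rel <- asn$relative_length[m]
    ## group consecutive genes (in genome order) sharing a best ref hit,
    ## tolerating one intervening gene
    grp <- cumsum(c(TRUE, !(d$ref[-1] == d$ref[-nrow(d)] &
                            !is.na(d$ref[-1]) & !is.na(d$ref[-nrow(d)]) &
                            diff(d$pos_in_genome) <= max_gap_rows + 1L)))
    for (g in split(seq_len(nrow(d)), grp)) {
      if (length(g) < 2L || is.na(d$ref[g[1]])) next
      tot <- sum(d$rel[g])
      if (is.na(tot)) next
      if (tot >= 100 * (1 - length_tolerance) &&
          tot <= 100 * (1 + length_tolerance)) {
        out[[length(out) + 1L]] <- data.frame(
          genome_id = gid, ref_gene = d$ref[g[1]],
          fragments = paste(d$gene_id[g], collapse = ";"),
          n_fragments = length(g), total_relative_length = tot)
      }
    }
  }
  splits <- if (length(out)) do.call(rbind, out) else
    data.frame(genome_id = character(0), ref_gene = character(0),
               fragments = character(0), n_fragments = integer(0),
               total_relative_length = numeric(0))
  rownames(splits) <- NULL
  list(splits = splits,
       internal_stop_candidates = internal_stop_candidates)
}

#' Direction changes and inversions in a gene array
#'
#' A gene whose strand disagrees with its row's majority strand is a
#' strand deviation. A maximal run of two or more such genes, consecutive
#' in their genome's order and occupying strictly descending rows (their
#' local order is reversed relative to the array), is an inversion;
#' isolated deviations are direction changes.
#'
#' @param array A `GeneArray`.
#' @return List with `direction_changes` (data.frame `genome_id,
#'   row_index, gene_id`) and `inversions` (data.frame `genome_id,
#'   start_row, end_row, size, gene_ids`).
#' @export
strand_deviations <- function(array) {
  ## per-row majority strand
  maj <- vapply(split(array$cells$strand, array$cells$row_index),
                function(s) names(sort(table(s), decreasing = TRUE))[1],
                character(1))
  dc <- list(); inv <- list()
  for (gid in array$genome_ids) {
    d <- array$cells[array$cells$genome_id == gid, ]
    d <- d[order(d$pos_in_genome), ]
    if (!nrow(d)) next
    flip <- d$strand != maj[as.character(d$row_index)]
    i <- 1L
    while (i <= nrow(d)) {
      if (!flip[i]) { i <- i + 1L; next }
      j <- i
      while (j < nrow(d) && flip[j + 1L] &&
             d$pos_in_genome[j + 1L] == d$pos_in_genome[j] + 1L &&
             d$row_index[j + 1L] < d$row_index[j]) j <- j + 1L
      if (j > i) {
        inv[[length(inv) + 1L]] <- data.frame(
          genome_id = gid,
          start_row = min(d$row_index[i:j]),
          end_row = max(d$row_index[i:j]),
          size = j - i + 1L,
          gene_ids = paste(d$gene_id[i:j], collapse = ";"))
      } else {
        dc[[length(dc) + 1L]] <- data.frame(
          genome_id = gid, row_index = d$row_index[i], gene_id = d$gene_id[i])
      }
      i <- j + 1L
    }
  }
  empty_dc <- data.frame(genome_id = character(0), row_index = integer(0),
                         gene_id = character(0))
  empty_inv <- data.frame(genome_id = character(0), start_row = integer(0),
                          end_row = integer(0), size = integer(0),
                          gene_ids = character(0))
  list(direction_changes = if (length(dc)) do.call(rbind, dc) else empty_dc,
       inversions = if (length(inv)) do.call(rbind, inv) else empty_inv)
}

#' Reconstruct reference syntenic blocks along a gene array
#'
#' Rows carrying a reference identity are scanned in array order; a block
#' extends while consecutive assigned rows map to consecutive reference
#' indices (strictly +1 for same orientation, -1 for reversed; repeats of
#' the same index, from fragment/duplicate rows, do not break a block).
#' Rows without an assignment are skipped without breaking a block by
#' default, so that badly deteriorated genes do not shatter blocks.
#'
#' @param array A `GeneArray`.
#' @param ref_order Character vector of reference gene ids in reference
#'   genomic order.
#' @param skip_unassigned Skip unassigned rows (default `TRUE`) instead of
#'   breaking blocks at them.
#' @return List with `blocks` (data.frame `start_row, end_row, ref_start,
#'   ref_end, orientation, size`) and `count`.
#' @export
syntenic_blocks <- function(array, ref_order, skip_unassigned = TRUE) {
  meta <- array$rows
  ridx <- match(meta$ref_gene, ref_order)
  rows <- which(!is.na(ridx))
  if (!length(rows)) stop("no rows carry a reference assignment")
  if (!skip_unassigned) {
    ## an unassigned row between two assigned rows breaks the chain
    breaks <- vapply(seq_along(rows)[-1], function(k)
      rows[k] - rows[k - 1L] > 1L, logical(1))
  } else breaks <- rep(FALSE, length(rows) - 1L)
  blocks <- list()
  start <- 1L; orient <- 0L
  flush <- function(from, to) {
    ix <- ridx[rows[from:to]]
    blocks[[length(blocks) + 1L]] <<- data.frame(
      start_row = rows[from], end_row = rows[to],
      ref_start = ix[1], ref_end = ix[length(ix)],
      orientation = if (orient < 0) "reversed" else "same",
      size = length(unique(ix)))
  }
  if (length(rows) > 1L) for (k in 2:length(rows)) {
    d <- ridx[rows[k]] - ridx[rows[k - 1L]]
    broke <- if (k - 1L >= 1L && length(breaks)) breaks[k - 1L] else FALSE
    ok <- !broke && (d == 0L || (orient == 0L && abs(d) == 1L) ||
                     (orient != 0L && d == orient))
    if (ok) {
      if (orient == 0L && d != 0L) orient <- d
    } else {
      flush(start, k - 1L)
      start <- k; orient <- 0L
    }
  }
  flush(start, length(rows))
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL
  list(blocks = blocks, count = nrow(blocks))
}

#' Binary presence/absence matrix of a gene array
#'
#' @param array A `GeneArray`.
#' @return Integer matrix (rows x genomes), entry 1 where the cell is
#'   non-empty, with row indices and genome ids as dimnames.
#' @export
presence_matrix <- function(array) {
  R <- nrow(array$rows); G <- length(array$genome_ids)
  m <- matrix(0L, R, G, dimnames = list(array$rows$row_index,
                                        array$genome_ids))
  ij <- cbind(array$cells$row_index,
              match(array$cells$genome_id, array$genome_ids))
  m[ij] <- 1L
  m
}

#' Write a gene array as TSV
#'
#' One row per array row: metadata columns followed by one column per
#' genome with cells formatted `gene_id(strand)` and `;`-joined when a
#' cell holds several genes.
#'
#' @param array A `GeneArray`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_array_tsv <- function(array, path) {
  meta <- array$rows
  for (gid in array$genome_ids) {
    d <- array$cells[array$cells$genome_id == gid, ]
    lab <- vapply(split(sprintf("%s(%s)", d$gene_id, d$strand), d$row_index),
                  paste, character(1), collapse = ";")
    col <- rep("", nrow(meta))
    col[as.integer(names(lab))] <- lab
    meta[[gid]] <- col
  }
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
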