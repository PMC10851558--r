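## Protein-level homology of endosymbiont genes to a free-living reference
## proteome: global affine-gap alignment, percent identity, relative length
## and reciprocal-best-hit assignment.

#' Load a substitution matrix by name
#'
#' Fetches the named matrix (e.g. `"BLOSUM62"`) from the matrices shipped
#' with Biostrings and returns it as a numeric matrix with residue dimnames.
#'
#' @param name Matrix name; default `"BLOSUM62"`.
#' @return Numeric matrix with identical row/column residue names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  storage.mode(m) <- "double"
  m
}

.clean_aa <- function(x) {
  ## non-standard residues are treated as X (matrix fallback score 0)
  chartr("UOJuoj*", "XXXXXXX", toupper(x))
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment maximizing the substitution-matrix
#' score with gap cost `gap_open + L * gap_extend` for a gap of length `L`
#' (the BLASTp convention at the defaults BLOSUM62/11/1). The traceback is
#' deterministic: on ties, match/mismatch is preferred over a gap in `b`,
#' which is preferred over a gap in `a`.
#'
#' @param a,b Amino-acid sequences (non-empty character scalars).
#' @param matrix Substitution matrix name or numeric matrix with residue
#'   dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `a_aln`, `b_aln` (gapped rows) and `score`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                         gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  sub <- if (is.character(matrix)) substitution_matrix(matrix) else matrix
  nw_align_cpp(.clean_aa(a), .clean_aa(b), sub, gap_open, gap_extend)
}

#' Alignment score only (same model as [global_align()])
#' @inheritParams global_align
#' @return Numeric score.
#' @export
align_score <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  sub <- if (is.character(matrix)) substitution_matrix(matrix) else matrix
  nw_score_cpp(.clean_aa(a), .clean_aa(b), sub, gap_open, gap_extend)
}

#' All-vs-all global alignment score matrix
#'
#' The global score is symmetric in its arguments, so a single matrix
#' serves both search directions of a reciprocal-best-hit run.
#'
#' @param queries,refs Named character vectors of amino-acid sequences.
#' @inheritParams global_align
#' @return Numeric matrix (queries x refs) with dimnames.
#' @export
align_score_matrix <- function(queries, refs, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  sub <- if (is.character(matrix)) substitution_matrix(matrix) else matrix
  m <- nw_score_matrix_cpp(.clean_aa(queries), .clean_aa(refs), sub,
                           gap_open, gap_extend)
  dimnames(m) <- list(names(queries), names(refs))
  m
}

#' Percent identity of a pairwise alignment
#'
#' Terminal-gap columns (leading/trailing columns where either row is a
#' gap) are trimmed; internal gap columns count in the denominator when
#' `denominator = "alignment"` (default). Alternatives divide by the
#' shorter or longer ungapped sequence length.
#'
#' @param alignment List with `a_aln` and `b_aln` (equal-length gapped
#'   rows), as returned by [global_align()].
#' @param denominator One of `"alignment"`, `"shorter"`, `"longer"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(alignment,
                             denominator = c("alignment", "shorter",
                                             "longer")) {
  denominator <- match.arg(denominator)
  a <- strsplit(alignment$a_aln, "")[[1]]
  b <- strsplit(alignment$b_aln, "")[[1]]
  if (length(a) != length(b) || !length(a))
    stop("alignment rows empty or of unequal length")
  gap <- a == "-" | b == "-"
  inner <- which(!gap)
  if (!length(inner)) stop("alignment has no aligned columns")
  len_a <- sum(a != "-"); len_b <- sum(b != "-")   # full ungapped lengths
  keep <- seq(min(inner), max(inner))   # trim terminal-gap columns
  a <- a[keep]; b <- b[keep]
  ident <- sum(a == b & a != "-")
  den <- switch(denominator,
    alignment = length(a),
    shorter = min(len_a, len_b),
    longer = max(len_a, len_b))
  if (den == 0) stop("zero-length trimmed alignment")
  100 * ident / den
}

#' Reciprocal-best-hit homolog assignment
#'
#' Every query protein is assigned its best-scoring reference protein
#' under global affine-gap alignment; ties are broken by percent identity,
#' then lexicographic gene id. An assignment is reciprocal when the two
#' genes are each other's best hit. Queries whose best score falls below
#' `min_score` are left unassigned (`ref_gene = NA`).
#'
#' @param query_proteome,ref_proteome Named character vectors of
#'   amino-acid sequences.
#' @param min_score Minimum alignment score for an assignment.
#' @param matrix,gap_open,gap_extend Alignment parameters, see
#'   [global_align()].
#' @param denominator Identity denominator, see [percent_identity()].
#' @return Data frame of `HomologAssignment` rows: `query_gene`,
#'   `ref_gene`, `score`, `identity`, `relative_length` (100 x query AA
#'   length / ref AA length) and `reciprocal`.
#' @export
reciprocal_best_hits <- function(query_proteome, ref_proteome,
                                 min_score = 40, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1,
                                 denominator = "alignment") {
  if (!length(query_proteome) || !length(ref_proteome))
    stop("both proteomes must be non-empty")
  sub <- if (is.character(matrix)) substitution_matrix(matrix) else matrix
  S <- align_score_matrix(query_proteome, ref_proteome, sub,
                          gap_open, gap_extend)
  qn <- names(query_proteome); rn <- names(ref_proteome)

  pick_best <- function(scores, cand_names, q, targets) {
    ## best by score; ties by identity to q, then lexicographic name
    best <- which(scores == max(scores))
    if (length(best) > 1L) {
      ids <- vapply(best, function(k) percent_identity(
        global_align(q, targets[[k]], sub, gap_open, gap_extend),
        denominator), numeric(1))
      best <- best[ids == max(ids)]
      if (length(best) > 1L) best <- best[order(cand_names[best])][1L]
    }
    best[1L]
  }

  best_ref <- integer(length(qn))
  for (i in seq_along(qn))
    best_ref[i] <- pick_best(S[i, ], rn, query_proteome[[i]], ref_proteome)
  best_query <- integer(length(rn))
  for (j in seq_along(rn))
    best_query[j] <- pick_best(S[, j], qn, ref_proteome[[j]], query_proteome)

  out <- data.frame(query_gene = qn, ref_gene = NA_character_,
                    score = NA_real_, identity = NA_real_,
                    relative_length = NA_real_, reciprocal = FALSE)
  for (i in seq_along(qn)) {
    j <- best_ref[i]
    sc <- S[i, j]
    if (sc < min_score) next
    aln <- global_align(query_proteome[[i]], ref_proteome[[j]], sub,
                        gap_open, gap_extend)
    out$ref_gene[i] <- rn[j]
    out$score[i] <- sc
    out$identity[i] <- percent_identity(aln, denominator)
    out$relative_length[i] <-
      100 * nchar(query_proteome[[i]]) / nchar(ref_proteome[[j]])
    out$reciprocal[i] <- best_query[j] == i
  }
  out
}

#' Write homolog assignments as TSV
#' @param assignments Output of [reciprocal_best_hits()], optionally with a
#'   `query_genome` column prepended.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
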