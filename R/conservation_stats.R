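## The %GC-versus-homolog-identity framework: quadrant classification,
## category overlays, correlations, and the multiple linear regression of
## identity on gene %GC and relative length.

#' Quadrant thresholds from a pooled gene set
#'
#' Thresholds default to the pooled means of the input set rather than the
#' published dataset-specific values; supply `gc_mean`/`identity_mean` to
#' pin them.
#'
#' @param table Data frame with columns `gc` and `identity`.
#' @param gc_mean,identity_mean Optional fixed thresholds.
#' @return List of class `QuadrantThresholds` with `gc_mean` and
#'   `identity_mean`.
#' @export
quadrant_thresholds <- function(table = NULL, gc_mean = NULL,
                                identity_mean = NULL) {
  if (is.null(gc_mean))
    gc_mean <- mean(table$gc[is.finite(table$gc)])
  if (is.null(identity_mean))
    identity_mean <- mean(table$identity[is.finite(table$identity)])
  stopifnot(is.finite(gc_mean), is.finite(identity_mean))
  structure(list(gc_mean = gc_mean, identity_mean = identity_mean),
            class = "QuadrantThresholds")
}

#' Classify genes into conservation quadrants
#'
#' Q1: above the %GC threshold, below the identity threshold (GC-rich but
#' deteriorated); Q2: below both; Q3: above both (conserved); Q4: below
#' the %GC threshold, above the identity threshold. Values exactly on a
#' threshold are assigned to the "above" side.
#'
#' @param gc,identity Numeric vectors (recycled to common length).
#' @param thresholds A `QuadrantThresholds`.
#' @return Character vector of `"Q1".."Q4"`.
#' @export
quadrant_classify <- function(gc, identity, thresholds) {
  gc_hi <- gc >= thresholds$gc_mean
  id_hi <- identity >= thresholds$identity_mean
  ifelse(gc_hi & id_hi, "Q3",
         ifelse(gc_hi & !id_hi, "Q1",
                ifelse(!gc_hi & id_hi, "Q4", "Q2")))
}

#' Quadrant counts for a gene category
#'
#' @param classified Data frame with columns `gene_id` and `quadrant`
#'   (from [quadrant_classify()]); gene ids may repeat across genomes.
#' @param category Character vector of gene ids (the overlay category);
#'   `NULL` counts all classified genes.
#' @return Named integer vector `Q1..Q4` summing to the number of
#'   classified category members; warns about category ids absent from
#'   the classified set.
#' @export
quadrant_summary <- function(classified, category = NULL) {
  d <- classified
  if (!is.null(category)) {
    missing <- setdiff(category, d$gene_id)
    if (length(missing))
      warning(length(missing), " category ids absent from classified set")
    d <- d[d$gene_id %in% category, , drop = FALSE]
  }
  counts <- table(factor(d$quadrant, levels = c("Q1", "Q2", "Q3", "Q4")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Multiple linear regression of homolog identity on %GC and length
#'
#' Ordinary least squares of `identity ~ gc + relative_length`, with
#' standardized coefficients (raw coefficient times SD(predictor) /
#' SD(response)) and per-coefficient two-sided t-test p-values.
#'
#' @param table Data frame with numeric columns `identity`, `gc`,
#'   `relative_length` (n >= 3, complete cases used).
#' @return List of class `RegressionFit` with `intercept`, `coef_gc`,
#'   `coef_len`, `standardized_coef_gc`, `standardized_coef_len`,
#'   `r_squared`, `p_values`, `conf_int` (95% for the raw coefficients)
#'   and `n`.
#' @export
fit_identity_model <- function(table) {
  d <- table[stats::complete.cases(table[, c("identity", "gc",
                                             "relative_length")]), ]
  if (nrow(d) < 3L) stop("need at least 3 complete rows")
  X <- cbind(1, d$gc, d$relative_length)
  if (qr(X)$rank < 3L) {
    r <- stats::cor(d$gc, d$relative_length)
    stop("rank-deficient design: gc and relative_length are collinear",
         if (is.finite(r)) sprintf(" (r = %.3f)", r) else
           " (a predictor is constant)")
  }
  fit <- stats::lm(identity ~ gc + relative_length, data = d)
  co <- stats::coef(fit)
  sy <- stats::sd(d$identity)
  std <- function(coef, x) if (sy > 0) coef * stats::sd(x) / sy else 0
  sm <- summary(fit)
  structure(list(
    intercept = unname(co[1]),
    coef_gc = unname(co["gc"]),
    coef_len = unname(co["relative_length"]),
    standardized_coef_gc = unname(std(co["gc"], d$gc)),
    standardized_coef_len = unname(std(co["relative_length"],
                                       d$relative_length)),
    r_squared = if (sy == 0) 0 else sm$r.squared,
    p_values = sm$coefficients[, "Pr(>|t|)"],
    conf_int = stats::confint(fit),
    n = nrow(d),
    model = fit), class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf(paste0("RegressionFit (n = %d): identity = %.3f + %.3f*gc",
                     " + %.3f*rel_len; R^2 = %.3f\n",
                     "standardized: gc %.3f, rel_len %.3f\n"),
              x$n, x$intercept, x$coef_gc, x$coef_len, x$r_squared,
              x$standardized_coef_gc, x$standardized_coef_len))
  invisible(x)
}

#' Pearson and Spearman correlation of %GC with homolog identity
#'
#' @param table Data frame with numeric columns `gc` and `identity`.
#' @return List with `pearson` and `spearman`, each holding `estimate`
#'   and `p_value`.
#' @export
gc_identity_correlation <- function(table) {
  d <- table[stats::complete.cases(table[, c("gc", "identity")]), ]
  if (nrow(d) < 3L) stop("need at least 3 complete rows")
  if (stats::sd(d$gc) == 0 || stats::sd(d$identity) == 0)
    stop("zero variance in gc or identity")
  pe <- stats::cor.test(d$gc, d$identity, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(d$gc, d$identity, method = "spearman"))
  list(pearson = list(estimate = unname(pe$estimate),
                      p_value = pe$p.value),
       spearman = list(estimate = unname(sp$estimate),
                       p_value = sp$p.value))
}
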