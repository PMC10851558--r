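## Independent oracles used across the suite. These deliberately avoid the
## package's own algorithms: alignment scores come from exhaustive path
## enumeration, clustering heights from a direct O(n^3) agglomeration,
## rank correlations from explicit rank arithmetic.

## Exhaustive global affine-gap alignment score: enumerate every monotone
## alignment path (match / gap-in-b / gap-in-a) and score it directly.
## Exponential; only for sequences of a handful of residues.
oracle_align_score <- function(a, b, sub, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, "M", acc + sub[av[i], bv[j]])
    if (i <= n)
      rec(i + 1L, j, "X", acc - (if (prev == "X") ext else open + ext))
    if (j <= m)
      rec(i, j + 1L, "Y", acc - (if (prev == "Y") ext else open + ext))
  }
  rec(1L, 1L, "S", 0)
  best
}

## Direct average-linkage agglomeration: at every step merge the pair of
## clusters with the smallest mean pairwise distance (ties by the
## lexicographically first label pair), recording merge heights.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; best_h <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

## Spearman rho from first principles: Pearson correlation of mid-ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean_x <- mean(rx); mean_y <- mean(ry)
  sum((rx - mean_x) * (ry - mean_y)) /
    sqrt(sum((rx - mean_x)^2) * sum((ry - mean_y)^2))
}

## Closed-form OLS via the normal equations, independent of lm().
oracle_ols <- function(y, X) {
  X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

## Ex90 oracle: cumulative sum over the sorted vector.
oracle_ex90 <- function(v, fraction = 0.9) {
  s <- sort(v, decreasing = TRUE)
  k <- 0L; acc <- 0
  repeat {
    k <- k + 1L
    acc <- acc + s[k]
    if (acc >= fraction * sum(v)) return(k)
  }
}
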