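#' @title Repression classes and feature statistics
#' @description Repression classification from proximal-isoform fold
#'   change (repressed: FC < 0.25; non-repressed: FC > 1; else
#'   intermediate), Spearman rank correlation with an exact permutation
#'   p-value at small n, the feature correlation matrix with
#'   average-linkage clustering, and the paired Wilcoxon signed-rank test.
#' @name feature_stats
NULL

#' Repression class from proximal-isoform abundance
#'
#' `FC = meiotic / premeiotic`; a gene is `repressed` when FC < 0.25,
#' `non_repressed` when FC > 1, `intermediate` otherwise (both inequalities
#' strict). Genes with zero premeiotic TPM are `NA` (flagged).
#'
#' @param tpm_a,tpm_b premeiotic and meiotic proximal TPM (vectors).
#' @param repressed_below,non_repressed_above the strict FC cutpoints.
#' @return character vector of classes.
#' @export
classify_repression <- function(tpm_a, tpm_b, repressed_below = 0.25,
                                non_repressed_above = 1) {
  fc <- tpm_b / tpm_a
  out <- rep("intermediate", length(fc))
  out[fc < repressed_below] <- "repressed"
  out[fc > non_repressed_above] <- "non_repressed"
  if (any(tpm_a == 0)) {
    warning("zero premeiotic TPM: repression class undefined for some genes")
    out[tpm_a == 0] <- NA_character_
  }
  out
}

.midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks for ties).
#' Incomplete pairs are dropped. The two-sided p-value uses the t
#' approximation for n > 10 and exact permutation enumeration (all n!
#' arrangements, tie-aware) for n <= 10.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_cor needs at least 3 complete pairs")
  rx <- .midrank(x); ry <- .midrank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  if (n > 10) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    p <- exact_perm_spearman_p(rx - mean(rx), ry - mean(ry))
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Pairwise Spearman correlation matrix with clustering
#'
#' Computes the pairwise-complete Spearman correlation over all numeric
#' feature columns, clusters features by average linkage on the distance
#' `1 - rho`, and returns the matrix in dendrogram leaf order. Features with
#' fewer than 3 complete pairs against every other feature are dropped with
#' a warning. Raw p-values are reported as-is; a Benjamini-Hochberg adjusted
#' copy is additionally returned (an extension over the plain analysis).
#'
#' @param features data.frame of per-gene features (numeric columns are
#'   used; a `gene_id`/character column is ignored).
#' @return list with `rho` and `p` matrices (leaf order), `p_adj`
#'   (Benjamini-Hochberg), `order` (leaf order of the original columns) and
#'   `hclust`.
#' @export
correlation_clustermap <- function(features) {
  df <- as.data.frame(features)
  num <- vapply(df, is.numeric, logical(1))
  df <- df[, num, drop = FALSE]
  usable <- vapply(df, function(col) sum(!is.na(col)) >= 3, logical(1))
  if (any(!usable)) {
    warning(sprintf("dropping feature(s) without enough complete pairs: %s",
                    paste(names(df)[!usable], collapse = ", ")))
    df <- df[, usable, drop = FALSE]
  }
  k <- ncol(df)
  if (k < 2) stop("need at least two usable features")
  rho <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(names(df), names(df))
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- spearman_cor(df[[i]], df[[j]])
    rho[i, j] <- rho[j, i] <- r$rho
    p[i, j] <- p[j, i] <- r$p
  }
  d <- 1 - rho
  d[is.na(d)] <- 1
  hc <- hclust(as.dist(d), method = "average")
  ord <- hc$order
  up <- upper.tri(p)
  p_adj <- p
  p_adj[up] <- stats::p.adjust(p[up], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(rho = rho[ord, ord], p = p[ord, ord], p_adj = p_adj[ord, ord],
       order = ord, labels = names(df)[ord], hclust = hc)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `b - a`; zero differences are
#' dropped. The statistic is the sum of ranks of positive differences. The
#' exact signed-rank null is used for n <= 25 without ties in |d|; a normal
#' approximation with continuity and tie correction otherwise. When all
#' differences are zero the test is degenerate (`p = 1`, flagged by a
#' warning).
#'
#' @param a,b paired numeric vectors (a = premeiotic, b = meiotic).
#' @return list with `statistic` (V, rank sum of positive differences),
#'   `p`, `n` (non-zero pairs) and `exact` flag.
#' @export
paired_wilcoxon <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  d <- (b - a)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n))
    return(list(statistic = v, p = min(p, 1), n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2)
  list(statistic = v, p = min(2 * pnorm(-abs(z)), 1), n = n, exact = FALSE)
}
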