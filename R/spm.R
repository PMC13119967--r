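# 1D Statistical Parametric Mapping for paired designs: pointwise paired t
# curves, exhaustive sign-flip permutation null, cluster-level inference and
# Benjamini-Hochberg FDR across variables.

#' Pointwise paired t curve
#'
#' At each node, computes the one-sample t statistic of the paired
#' differences `a - b`: `t = mean(d) / (sd(d)/sqrt(n))` with the sample
#' (n-1) standard deviation. Nodes with zero variance yield t = 0 when the
#' mean is also zero and +/-Inf sentinels otherwise; the sentinels order
#' above any finite t in all downstream comparisons.
#'
#' @param a,b n x q matrices of matched curves (rows = subjects, in the same
#'   order).
#' @return numeric vector of q t values.
#' @export
paired_t_curve <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("curve matrices must have identical dimensions", call. = FALSE)
  if (nrow(a) < 2L) stop("need at least 2 paired subjects", call. = FALSE)
  t_from_diff(a - b)
}

# t curve of an n x q difference matrix, with zero-variance sentinels
t_from_diff <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  se <- sqrt(apply(d, 2, stats::var) / n)
  tt <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  as.numeric(tt)
}

# longest run of TRUE in a logical vector (0 if none)
max_run <- function(flag) {
  r <- rle(flag)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Sign-flip permutation SPM inference for paired difference curves
#'
#' Enumerates all `2^n` sign assignments to the subjects' difference curves
#' (the exact null distribution under side exchangeability), computes the t
#' curve of each, and takes the cluster-forming threshold as the
#' `(1 - alpha)` quantile of the permutation distribution of the maximum
#' absolute t over the curve. Observed clusters are maximal contiguous runs
#' with `|t|` above the threshold; each cluster's p-value is the fraction of
#' permutations whose longest supra-threshold run *in the cluster's
#' direction* (signed t above the threshold, the default directional
#' counting) is at least as long as the observed cluster. With exhaustive
#' enumeration every p is a multiple of `1/2^n` and the smallest attainable
#' value is `1/2^n`. The inclusive alternative (`counting = "two_sided"`,
#' runs of `|t|`, minimum `2/2^n`) is available for comparison.
#'
#' @param diff n x q matrix of paired difference curves (more- minus
#'   less-impaired side).
#' @param alpha significance level for the cluster-forming threshold,
#'   default 0.05.
#' @param counting `"directional"` (default) or `"two_sided"` permutation
#'   counting for cluster p-values.
#' @param exhaustive enumerate all `2^n` sign flips (default). Requires
#'   `2^n <= cap`.
#' @param cap largest permitted exhaustive enumeration, default `2^20`.
#' @param n_iter Monte-Carlo sample size when `exhaustive = FALSE` (the
#'   identity assignment is always included).
#' @param seed seed for Monte-Carlo sampling.
#' @return object of class `spm_result`: list with `t` (q observed t
#'   values), `crit`, `clusters` (data.frame: `node_start`, `node_end` as
#'   0-based nodes, `extent`, `direction`, `p`), `n`, `n_permutations`,
#'   `alpha`, `counting`.
#' @export
spm_paired_permutation <- function(diff, alpha = 0.05,
                                   counting = c("directional", "two_sided"),
                                   exhaustive = TRUE, cap = 2^20,
                                   n_iter = 10000L, seed = NULL) {
  counting <- match.arg(counting)
  d <- as.matrix(diff)
  n <- nrow(d); q <- ncol(d)
  if (n < 2L) stop("need at least 2 paired subjects", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  if (exhaustive) {
    if (2^n > cap)
      stop("exhaustive enumeration of 2^", n, " sign flips exceeds the cap; ",
           "set exhaustive = FALSE with n_iter and a seed for Monte-Carlo ",
           "inference", call. = FALSE)
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))  # row 1 = identity
  } else {
    if (!is.null(seed)) set.seed(seed)
    S <- matrix(sample(c(1, -1), (n_iter - 1L) * n, replace = TRUE),
                ncol = n)
    S <- rbind(rep(1, n), S)
  }
  M <- nrow(S)
  ss <- colSums(d^2)                       # invariant under sign flips
  mn <- (S %*% d) / n
  vr <- sweep(-n * mn^2, 2, ss, "+") / (n - 1)
  vr[vr < 0] <- 0                          # numerical guard
  se <- sqrt(vr / n)
  tmat <- mn / se
  tmat[se == 0 & mn == 0] <- 0
  tmat[se == 0 & mn != 0] <- sign(mn[se == 0 & mn != 0]) * Inf
  t_obs <- as.numeric(tmat[1L, ])

  amax <- apply(abs(tmat), 1, max)
  crit <- sort(amax)[ceiling((1 - alpha) * M)]

  above <- abs(t_obs) > crit
  clusters <- data.frame(node_start = integer(0), node_end = integer(0),
                         extent = integer(0), direction = integer(0),
                         p = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    Lpos <- apply(tmat, 1, function(tt) max_run(tt > crit))
    Lneg <- if (counting == "directional")
      apply(tmat, 1, function(tt) max_run(tt < -crit)) else NULL
    Labs <- if (counting == "two_sided")
      apply(tmat, 1, function(tt) max_run(abs(tt) > crit)) else NULL
    rows <- lapply(keep, function(j) {
      i0 <- starts[j]; i1 <- ends[j]
      ext <- i1 - i0 + 1L
      dirn <- sign(t_obs[i0])
      cnt <- switch(counting,
                    directional = if (dirn >= 0) sum(Lpos >= ext)
                                  else sum(Lneg >= ext),
                    two_sided = sum(Labs >= ext))
      data.frame(node_start = i0 - 1L, node_end = i1 - 1L, extent = ext,
                 direction = dirn, p = cnt / M)
    })
    clusters <- do.call(rbind, rows)
  }
  structure(list(t = t_obs, crit = crit, clusters = clusters, n = n,
                 n_permutations = M, alpha = alpha, counting = counting,
                 exhaustive = exhaustive),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("spm_result: n = %d, %d permutations (%s), crit |t| = %.3f\n",
              x$n, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$crit))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: nodes %d-%d (extent %d, %s), p = %.4g\n",
                  i, x$clusters$node_start[i], x$clusters$node_end[i],
                  x$clusters$extent[i],
                  if (x$clusters$direction[i] >= 0) "MI > LI" else "MI < LI",
                  x$clusters$p[i]))
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR decisions across variables
#'
#' Applies the Benjamini-Hochberg step-up procedure (via
#' [stats::p.adjust()]) to one p-value per variable and flags the rejected
#' hypotheses at level `alpha`.
#'
#' @param p named numeric vector of p-values (e.g. the minimum cluster p per
#'   variable within one condition).
#' @param alpha FDR level, default 0.05.
#' @return data.frame with `variable`, `p`, `p_adj`, `reject`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0L)
    return(data.frame(variable = character(0), p = numeric(0),
                      p_adj = numeric(0), reject = logical(0)))
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(variable = if (is.null(names(p))) seq_along(p) else names(p),
             p = as.numeric(p), p_adj = as.numeric(adj),
             reject = adj <= alpha, row.names = NULL)
}
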