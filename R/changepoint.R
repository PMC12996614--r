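#' Automatic breakpoint determination from an expression profile
#'
#' Fits a piecewise-constant (two-mean step) model to the log2-transformed
#' per-exon sense depths and returns the changepoint minimising the residual
#' sum of squares. For a single changepoint over a gene-sized number of
#' exons the exhaustive scan over all n-1 candidate boundaries is exact, so
#' no iterative segmented fitter is needed. Coverage is multiplicative, so
#' the fit is on `y = log2(depth + epsilon)` rather than raw depth.
#'
#' The RSS of boundary k is
#' `sum_{i<=k} (y_i - mean(y_1..k))^2 + sum_{i>k} (y_i - mean(y_{k+1}..n))^2`;
#' the gain is relative to the one-mean (no-step) fit. Ties are broken
#' toward the smallest k.
#'
#' @param exonMeans per-exon sense mean depths in transcription order
#'   (at least 4 exons).
#' @param epsilon pseudocount before the log transform (default 0.05).
#' @return a list with `boundaryExon` (the best k), `rssGain`
#'   (RSS_null - RSS(k), >= 0) and `rss` (the full RSS profile over k).
#' @examples
#' autoBreakpoint(c(0, 0, 0, 8, 8, 8))$boundaryExon  # 3
#' @export
autoBreakpoint <- function(exonMeans, epsilon = 0.05) {
    n <- length(exonMeans)
    if (n < 4L)
        stop("automatic breakpoint determination needs at least 4 exons, got ",
             n)
    if (any(exonMeans < 0) || any(!is.finite(exonMeans)))
        stop("exon means must be finite and non-negative")
    y <- log2(exonMeans + epsilon)
    cs <- cumsum(y)
    cs2 <- cumsum(y^2)
    tot <- cs[n]
    tot2 <- cs2[n]
    k <- seq_len(n - 1L)
    # RSS(k) = sum(y^2) - S_left^2/k - S_right^2/(n-k)
    rss <- tot2 - cs[k]^2 / k - (tot - cs[k])^2 / (n - k)
    rssNull <- tot2 - tot^2 / n
    best <- which.min(rss)  # which.min takes the first minimum: smallest k
    list(boundaryExon = best,
         rssGain = max(0, rssNull - rss[best]),
         rss = rss)
}
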