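#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (with a
#' positive geometric mean across samples) of the ratio between the
#' feature's count and its geometric mean; factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)  # features positive in every sample
  if (!any(use))
    stop("no feature has a nonzero count in every sample; ",
         "consider a pseudo-reference fallback")
  s <- apply(counts, 2L, function(col) median(col[use] / exp(logg[use])))
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

#' Per-feature negative-binomial dispersion
#'
#' Method-of-moments dispersion on size-factor-normalised counts,
#' `max(0, (var - mean) / mean^2)`, with the variance pooled within
#' conditions. A mean-dispersion trend `a1/mu + a0` is fitted across
#' features and the working dispersion is the maximum of the per-feature
#' estimate and the trend (floored at 1e-8): noisy per-feature estimates
#' at small replicate numbers underestimate dispersion for many features,
#' which inflates Wald false positives, so falling below the trend is not
#' allowed while genuinely overdispersed features keep their larger
#' estimate. All-zero features get `NA` (untestable).
#'
#' @param counts features x samples count matrix.
#' @param size_factors from [estimate_size_factors()].
#' @param condition factor/vector of two condition labels per sample.
#' @return data.frame with `mean`, `dispersion_mom`, `dispersion_trend`,
#'   `dispersion` per feature.
#' @export
estimate_dispersions <- function(counts, size_factors, condition) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (any(table(condition) < 2L))
    stop("at least 2 replicates per condition are required")
  norm <- sweep(counts, 2L, size_factors, "/")
  k <- nlevels(condition); n <- ncol(norm)
  mu <- rowMeans(norm)
  ss <- rep(0, nrow(norm))
  for (lv in levels(condition)) {
    x <- norm[, condition == lv, drop = FALSE]
    ss <- ss + rowSums((x - rowMeans(x))^2)
  }
  v <- ss / (n - k)
  mom <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), NA_real_)
  pos <- !is.na(mom) & mom > 0 & mu > 0
  if (sum(pos) >= 5L) {
    fit <- lm(mom[pos] ~ I(1 / mu[pos]))
    a0 <- max(coef(fit)[1], 1e-8)
    a1 <- max(coef(fit)[2], 0)
    trend <- a1 / mu + a0
  } else {
    trend <- rep(if (any(pos)) mean(mom[pos]) else 1e-8, nrow(norm))
  }
  disp <- pmax(pmax(mom, trend), 1e-8)
  disp[is.na(mom)] <- NA_real_
  data.frame(mean = mu, dispersion_mom = mom,
             dispersion_trend = trend, dispersion = disp)
}

# one-feature NB GLM (log link, known dispersion alpha) by IRLS;
# design: intercept + condition indicator, offset log(size factor)
nb_irls <- function(y, x, offset, alpha, maxit = 100L, tol = 1e-8) {
  X <- cbind(1, x)
  beta <- c(log(mean(y / exp(offset)) + 1e-8), 0)
  XtWX <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta + offset)
    mu <- pmax(mu, 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    XtW <- t(X * w)
    XtWX <- XtW %*% X
    beta_new <- tryCatch(solve(XtWX, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    if (max(abs(beta_new - beta)) < tol) {
      beta <- as.vector(beta_new); converged <- TRUE; break
    }
    beta <- as.vector(beta_new)
    if (any(abs(beta) > 50)) break  # diverging (e.g. a group of all zeros)
  }
  if (!converged || is.null(XtWX))
    return(list(converged = FALSE, beta = c(NA, NA), se = NA_real_))
  se <- sqrt(diag(solve(XtWX)))[2]
  list(converged = TRUE, beta = beta, se = se)
}

#' Negative-binomial Wald test for a two-condition design
#'
#' Fits, per feature, an NB GLM with log link, a condition indicator and
#' log size factors as offsets, by iteratively reweighted least squares
#' with the dispersion fixed at the [estimate_dispersions()] value. The
#' Wald p-value comes from the normal approximation on the condition
#' coefficient. BH-adjusted p-values are reported alongside; the
#' differential call itself uses the raw p-value (the "more than twofold,
#' p < 0.05" rule): `call = |log2FC| > lfc_threshold & p < alpha`.
#' Features with all-zero counts (or non-converging fits) are untestable:
#' they get `NA` and are excluded from the BH denominator.
#'
#' @param counts features x samples count matrix.
#' @param condition two-level factor per sample; the *second* level is the
#'   numerator of the fold change (convention: control first, depleted
#'   second).
#' @param size_factors optional; computed if missing.
#' @param dispersions optional; computed if missing.
#' @param lfc_threshold log2 fold-change threshold for the call (1 =
#'   twofold).
#' @param alpha raw p-value threshold for the call.
#' @return data.frame: `feature`, `baseMean`, `log2FoldChange`, `lfcSE`,
#'   `stat`, `pvalue`, `padj`, `call`.
#' @export
nb_wald_test <- function(counts, condition, size_factors = NULL,
                         dispersions = NULL, lfc_threshold = 1,
                         alpha = 0.05) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("two-condition design required")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, size_factors, condition)
  x <- as.integer(condition == levels(condition)[2])
  offset <- log(size_factors)
  nfeat <- nrow(counts)
  l2fc <- se <- stat <- pval <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    a <- dispersions$dispersion[i]
    if (is.na(a) || all(counts[i, ] == 0)) next
    fit <- nb_irls(counts[i, ], x, offset, a)
    if (!fit$converged) next
    l2fc[i] <- fit$beta[2] / log(2)
    se[i] <- fit$se / log(2)
    stat[i] <- fit$beta[2] / fit$se
    pval[i] <- 2 * pnorm(-abs(stat[i]))
  }
  padj <- adjust_bh(pval)
  call <- !is.na(pval) & abs(l2fc) > lfc_threshold & pval < alpha
  data.frame(
    feature = rownames(counts) %||% as.character(seq_len(nfeat)),
    baseMean = rowMeans(sweep(counts, 2L, size_factors, "/")),
    log2FoldChange = l2fc, lfcSE = se, stat = stat,
    pvalue = pval, padj = padj, call = call,
    stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; `NA` p-values are excluded
#' from the denominator and propagate as `NA`.
#'
#' @param p numeric vector of p-values in \[0,1\] (NA allowed).
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  pp <- p[ok]
  o <- order(pp, decreasing = TRUE)
  q <- pmin(1, cummin(pp[o] * m / (m:1)))
  out[ok[o]] <- q
  out
}
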