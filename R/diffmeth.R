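#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for every feature with nonzero
#' counts in all samples, the ratio of its count to its across-sample
#' geometric mean is formed, and a sample's factor is the median of its
#' ratios. Factors are rescaled to geometric mean 1.
#'
#' @param m A [feature_count_matrix()] or plain counts matrix.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "feature_count_matrix")) m$counts else as.matrix(m)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    stop("no feature has nonzero counts in every sample; ",
         "median-of-ratios undefined (consider a pseudo-reference)")
  }
  lc <- log(counts[use, , drop = FALSE])
  loggeo <- rowMeans(lc)
  logs <- apply(lc - loggeo, 2, stats::median)
  s <- exp(logs - mean(logs))
  setNames(s, colnames(counts))
}

#' Method-of-moments NB dispersions with trend shrinkage
#'
#' Per-feature dispersion of the NB model `var = mu + alpha * mu^2`,
#' estimated on size-factor-normalized counts. Within each group the
#' moment estimate `(var - mean) / mean^2` is formed, pooled across
#' groups by degrees of freedom, and floored at `alpha_floor`. Raw
#' estimates are then shrunk toward a fitted mean-dispersion trend
#' `alpha(mu) = a1 / mu + a0` by weighted averaging in log space.
#'
#' @param m A [feature_count_matrix()].
#' @param s Size factors from [size_factors()] (computed if NULL).
#' @param groups Per-sample group labels (default `m$group`).
#' @param alpha_floor Minimum dispersion (default 1e-8).
#' @param trend_weight Weight of the trend in the log-space average,
#'   in `[0, 1]` (default 0.5; 0 = raw moments, 1 = pure trend).
#' @return Named numeric vector of per-feature dispersions.
#' @export
estimate_dispersions <- function(m, s = NULL, groups = NULL,
                                 alpha_floor = 1e-8, trend_weight = 0.5) {
  stopifnot(inherits(m, "feature_count_matrix"))
  if (is.null(s)) s <- size_factors(m)
  if (is.null(groups)) groups <- m$group
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("each group needs at least 2 samples to estimate dispersion")
  }
  norm <- sweep(m$counts, 2, s, "/")
  num <- 0
  den <- 0
  for (g in names(tab)) {
    cols <- groups == g
    mu_g <- rowMeans(norm[, cols, drop = FALSE])
    v_g <- apply(norm[, cols, drop = FALSE], 1, stats::var)
    w <- sum(cols) - 1
    term <- ifelse(mu_g > 0, (v_g - mu_g) / mu_g^2, NA)
    num <- num + ifelse(is.na(term), 0, w * term)
    den <- den + ifelse(is.na(term), 0, w)
  }
  raw <- pmax(alpha_floor, ifelse(den > 0, num / den, alpha_floor))
  mu <- rowMeans(norm)
  # trend fitted on informative features only; degenerate fits fall back
  # to the raw estimates
  fit_ok <- raw > alpha_floor & mu > 0
  alpha_tr <- rep(alpha_floor, length(raw))
  if (sum(fit_ok) >= 10) {
    co <- stats::coef(stats::lm(raw[fit_ok] ~ I(1 / mu[fit_ok])))
    a0 <- max(0, co[1])
    a1 <- max(0, co[2])
    alpha_tr <- pmax(alpha_floor, a0 + a1 / pmax(mu, 1e-8))
  }
  out <- exp((1 - trend_weight) * log(raw) + trend_weight * log(alpha_tr))
  setNames(pmax(alpha_floor, out), rownames(m$counts))
}

# NB deviance, parameterized by dispersion a (a > 0)
.nb_deviance <- function(y, mu, a) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / a) * log((1 + a * y) / (1 + a * mu))
  2 * rowSums(t1 - t2)
}

#' Negative-binomial Wald test for two-group differential methylation
#'
#' Fits, per feature, the NB generalized linear model
#' `mu_ij = s_j * 2^(b0_i + b1_i * x_j)` (`x_j = 1` for case samples)
#' by iteratively reweighted least squares with known per-feature
#' dispersion, and tests `b1 = 0` with a Wald z statistic using the
#' standard error from the expected Fisher information. P-values are
#' BH-adjusted; calls are flagged at `q < q_max` and fold change gated at
#' `|FC| > fc_min` (both strict).
#'
#' @param m A [feature_count_matrix()] with exactly two groups.
#' @param s Size factors (computed if NULL).
#' @param dispersions Per-feature dispersions (computed if NULL).
#' @param ref Reference (control) group label; defaults to `"control"`
#'   when present, else the alphabetically first label.
#' @param q_max,fc_min Calling thresholds (defaults 0.1 and 2).
#' @param max_iter,tol IRLS iteration cap and absolute deviance-change
#'   convergence tolerance.
#' @return An object of class `nb_diffmeth`: list with `results` (data
#'   frame: feature_id, base_mean, log2fc, se, stat, pvalue, qvalue,
#'   direction, is_dmr, is_fc_pass, converged), `size_factors`,
#'   `dispersions` and `params`. Non-converged features carry `NA`
#'   p-values and are excluded from the BH adjustment.
#' @export
nb_wald_test <- function(m, s = NULL, dispersions = NULL, ref = NULL,
                         q_max = 0.1, fc_min = 2,
                         max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(m, "feature_count_matrix"))
  lv <- sort(unique(m$group))
  if (length(lv) != 2) stop("exactly two groups required, got: ",
                            paste(lv, collapse = ", "))
  if (any(table(m$group) < 2)) stop("each group needs n >= 2")
  if (is.null(ref)) ref <- if ("control" %in% lv) "control" else lv[1]
  if (!ref %in% lv) stop("reference label '", ref, "' not in groups")
  if (is.null(s)) s <- size_factors(m)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(m, s)

  y <- m$counts
  nf <- nrow(y)
  x <- as.numeric(m$group != ref)
  off <- matrix(log(s), nf, ncol(y), byrow = TRUE)
  a <- as.numeric(dispersions)
  norm <- sweep(y, 2, s, "/")
  mu_ctrl <- rowMeans(norm[, x == 0, drop = FALSE])
  mu_case <- rowMeans(norm[, x == 1, drop = FALSE])
  b0 <- log(mu_ctrl + 0.5)
  b1 <- log(mu_case + 0.5) - b0

  xm <- matrix(x, nf, ncol(y), byrow = TRUE)
  dev_old <- rep(Inf, nf)
  active <- rep(TRUE, nf)
  converged <- rep(FALSE, nf)
  Sw <- Swx <- det <- rep(NA_real_, nf)
  for (it in seq_len(max_iter)) {
    eta <- off + b0 + b1 * xm
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    W <- mu / (1 + a * mu)
    z <- (eta - off) + (y - mu) / mu
    Sw_i <- rowSums(W)
    Swx_i <- rowSums(W * xm)
    Swz <- rowSums(W * z)
    Swxz <- rowSums(W * xm * z)
    det_i <- Sw_i * Swx_i - Swx_i^2   # x binary: sum(W x^2) = sum(W x)
    upd <- active & det_i > 1e-12
    b0[upd] <- ((Swx_i * Swz - Swx_i * Swxz) / det_i)[upd]
    b1[upd] <- ((Sw_i * Swxz - Swx_i * Swz) / det_i)[upd]
    Sw[upd] <- Sw_i[upd]
    Swx[upd] <- Swx_i[upd]
    det[upd] <- det_i[upd]
    eta <- off + b0 + b1 * xm
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    dev <- .nb_deviance(y, mu, a)
    done <- active & (abs(dev - dev_old) < tol)
    converged[done] <- TRUE
    active <- active & !done
    dev_old <- dev
    if (!any(active)) break
  }
  se_nat <- sqrt(Sw / det)
  log2fc <- b1 / log(2)
  se <- se_nat / log(2)
  stat <- b1 / se_nat
  pvalue <- 2 * stats::pnorm(-abs(stat))
  pvalue[!converged | !is.finite(stat)] <- NA
  qvalue <- bh_adjust(pvalue)
  res <- data.frame(
    feature_id = rownames(y),
    base_mean = rowMeans(norm),
    log2fc = log2fc, se = se, stat = stat,
    pvalue = pvalue, qvalue = qvalue,
    direction = ifelse(log2fc > 0, "hyper", "hypo"),
    is_dmr = !is.na(qvalue) & qvalue < q_max,
    is_fc_pass = abs(log2fc) > log2(fc_min),
    converged = converged,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = res, size_factors = s, dispersions = dispersions,
                 params = list(ref = ref, q_max = q_max, fc_min = fc_min,
                               groups = table(m$group))),
            class = "nb_diffmeth")
}

#' @export
print.nb_diffmeth <- function(x, ...) {
  r <- x$results
  cat("Negative-binomial Wald differential methylation\n")
  cat(sprintf("  %d features; groups: %s (reference: %s)\n", nrow(r),
              paste(sprintf("%s=%d", names(x$params$groups),
                            x$params$groups), collapse = ", "),
              x$params$ref))
  cat(sprintf("  DMRs at q < %g: %d (%d hyper, %d hypo)\n",
              x$params$q_max, sum(r$is_dmr, na.rm = TRUE),
              sum(r$is_dmr & r$direction == "hyper", na.rm = TRUE),
              sum(r$is_dmr & r$direction == "hypo", na.rm = TRUE)))
  cat(sprintf("  passing |FC| > %g as well: %d\n", x$params$fc_min,
              sum(r$is_dmr & r$is_fc_pass, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.nb_diffmeth <- function(object, ...) {
  r <- object$results
  calls <- call_dmcgi(object)
  out <- list(n_features = nrow(r),
              n_tested = sum(!is.na(r$pvalue)),
              n_dmr = sum(r$is_dmr, na.rm = TRUE),
              n_hyper = length(calls$hyper),
              n_hypo = length(calls$hypo),
              log2fc_range = range(r$log2fc, finite = TRUE))
  class(out) <- "summary.nb_diffmeth"
  out
}

#' @export
print.summary.nb_diffmeth <- function(x, ...) {
  cat(sprintf(paste0("%d features (%d tested): %d DMRs, of which %d hyper",
                     " and %d hypo pass the fold-change gate\n"),
              x$n_features, x$n_tested, x$n_dmr, x$n_hyper, x$n_hypo))
  invisible(x)
}

#' @export
coef.nb_diffmeth <- function(object, ...) {
  setNames(object$results$log2fc, object$results$feature_id)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' BH q-values with missing entries excluded from the number of tests
#' and returned as `NA` in place.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5)) # 0.04 0.04 0.04 0.50
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

.dm_results <- function(x) {
  if (inherits(x, "nb_diffmeth")) x$results else as.data.frame(x)
}

#' Call differentially methylated CpG islands
#'
#' Applies the two strict gates: `q < q_max` and fold change above
#' `fc_min` (hyper) or below `1/fc_min` (hypo).
#'
#' @param results An `nb_diffmeth` object or its results data frame.
#' @param q_max,fc_min Thresholds (defaults 0.1 and 2, both strict).
#' @return List with sorted `hyper` and `hypo` feature-id vectors.
#' @export
call_dmcgi <- function(results, q_max = 0.1, fc_min = 2) {
  r <- .dm_results(results)
  sig <- !is.na(r$qvalue) & r$qvalue < q_max
  list(hyper = sort(r$feature_id[sig & r$log2fc > log2(fc_min)]),
       hypo = sort(r$feature_id[sig & r$log2fc < -log2(fc_min)]))
}

#' Top differential features by fold change
#'
#' Ranks called hypermethylated islands by descending log2 fold change,
#' breaking ties by ascending q-value and then feature id.
#'
#' @param results An `nb_diffmeth` object or results data frame.
#' @param k Number of features to return.
#' @param candidates Optional feature-id pool to rank; defaults to the
#'   hypermethylated calls of [call_dmcgi()] at the default thresholds.
#' @return Character vector of `k` feature ids, best first.
#' @export
top_features <- function(results, k, candidates = NULL) {
  r <- .dm_results(results)
  if (is.null(candidates)) candidates <- call_dmcgi(r)$hyper
  r <- r[r$feature_id %in% candidates, , drop = FALSE]
  if (k > nrow(r)) {
    stop("k = ", k, " exceeds the ", nrow(r), " available features")
  }
  ord <- order(-r$log2fc, r$qvalue, r$feature_id)
  r$feature_id[ord][seq_len(k)]
}
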