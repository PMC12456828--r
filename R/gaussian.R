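#' Regularized Gaussian screening of candidate regions
#'
#' The informativity vectors of the hotspot (seed) regions define a
#' multivariate Gaussian "known region" distribution. Each candidate is
#' screened by its squared Mahalanobis distance from that distribution's
#' mean: under multivariate normality D^2 is chi-squared with d degrees of
#' freedom, so candidates with D^2 <= chi^2(1 - alpha, d) are accepted as
#' panel expansions and the rest rejected as outliers. An exponential-decay
#' prior score exp(-D / T), T = chi^2(1 - alpha, d), ranks accepted
#' candidates (used for budgeting only, never for acceptance).
#'
#' @name gaussian_screen
NULL

#' Fit a regularized multivariate Gaussian
#'
#' Mean = column means; covariance = unbiased (n - 1) sample covariance
#' plus `epsilon` on the diagonal, which keeps the matrix positive-definite
#' even when n <= d or features are collinear.
#'
#' @param X n-by-d matrix of known-region informativity vectors, n >= 2.
#' @param epsilon diagonal regularization (default 1e-6).
#' @param alpha significance level of the acceptance threshold.
#' @return an `mrd_gaussian`: list with `mu`, `sigma`, `chol` (upper
#'   Cholesky factor), `d`, `epsilon`, `alpha`, `chi2_threshold`.
#' @export
fit_gaussian <- function(X, epsilon = 1e-6, alpha = 0.05) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("fit_gaussian needs at least 2 rows")
  if (!all(is.finite(X))) stop("fit_gaussian: non-finite entries in X")
  d <- ncol(X)
  mu <- colMeans(X)
  sigma <- stats::cov(X) + diag(epsilon, d)
  ch <- chol(sigma) # errors if not positive-definite
  structure(list(mu = mu, sigma = sigma, chol = ch, d = d,
                 epsilon = epsilon, alpha = alpha,
                 chi2_threshold = chi2_critical(alpha, d)),
            class = "mrd_gaussian")
}

#' @export
print.mrd_gaussian <- function(x, ...) {
  cat("<mrd_gaussian> d = ", x$d, ", alpha = ", x$alpha,
      ", chi2 threshold = ", signif(x$chi2_threshold, 6), "\n", sep = "")
  invisible(x)
}

#' Squared Mahalanobis distance under a fitted model
#'
#' Solved through the stored Cholesky factor (forward substitution), never
#' an explicit matrix inverse.
#'
#' @param x numeric vector of length d, or an n-by-d matrix of rows.
#' @param model an `mrd_gaussian`.
#' @return non-negative real (or vector, one per row).
#' @export
mahalanobis_sq <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$d) {
    stop("dimension mismatch: x has ", ncol(x), " columns, model d = ",
         model$d)
  }
  centered <- sweep(x, 2L, model$mu)
  # sigma = R'R  =>  D^2 = || R^-T (x - mu) ||^2
  z <- backsolve(model$chol, t(centered), transpose = TRUE)
  colSums(z^2)
}

#' Chi-squared critical value
#'
#' The (1 - alpha) quantile of the chi-squared distribution with `d`
#' degrees of freedom.
#'
#' @param alpha significance level in (0, 1).
#' @param d degrees of freedom (feature dimension), >= 1.
#' @return positive real.
#' @export
chi2_critical <- function(alpha, d) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (d < 1L) stop("d must be >= 1")
  stats::qchisq(1 - alpha, df = d)
}

#' Exponential-decay prior score
#'
#' `exp(-sqrt(d2) / T)`: 1 at the distribution center, decaying with the
#' (unsquared) Mahalanobis distance, normalized by the chi-squared critical
#' value `T`. Used only to rank candidates; acceptance is the threshold
#' test.
#'
#' @param d2 squared Mahalanobis distance(s), >= 0.
#' @param T normalizing constant > 0 (the chi-squared critical value).
#' @return score(s) in (0, 1].
#' @export
prior_score <- function(d2, T) {
  if (any(T <= 0)) stop("T must be > 0")
  if (any(d2 < 0)) stop("d2 must be >= 0")
  exp(-sqrt(d2) / T)
}

#' Screen candidates against the fitted Gaussian
#'
#' @param model an `mrd_gaussian`.
#' @param candidates data.frame carrying candidate intervals (`chrom`,
#'   `start`, `end`, ...).
#' @param vectors matrix of candidate informativity vectors, one row per
#'   candidate, d columns.
#' @return `candidates` with `d2`, `prior` and `accepted` columns, sorted
#'   by prior descending (ties by genomic coordinate).
#' @export
screen_candidates <- function(model, candidates, vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != nrow(candidates)) {
    stop("candidates and vectors must have the same number of rows")
  }
  d2 <- if (nrow(vectors) > 0L) mahalanobis_sq(vectors, model) else numeric(0)
  out <- candidates
  out$d2 <- d2
  out$prior <- prior_score(d2, model$chi2_threshold)
  out$accepted <- d2 <= model$chi2_threshold
  ord <- order(-out$prior, out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a capture panel from hotspots and screened expansions
#'
#' The panel always contains the merged hotspot regions. Accepted expansion
#' regions are admitted in descending prior order; with a base-pair budget,
#' an expansion is admitted only while the cumulative *new* bases it adds
#' stay within `budget_bp`. Overlapping intervals are merged and the result
#' sorted; merged regions overlapping a hotspot keep `hotspot` provenance,
#' the rest are `expanded`.
#'
#' @param hotspots interval data.frame of seed regions.
#' @param decisions output of [screen_candidates()] (only `accepted` rows
#'   are used).
#' @param budget_bp optional cap on total added expansion bases.
#' @return an `mrd_panel`: list with `regions` (sorted merged intervals +
#'   `provenance`) and `total_length_bp`.
#' @export
assemble_panel <- function(hotspots, decisions, budget_bp = NULL) {
  if (!is.null(budget_bp) && budget_bp < 0) stop("budget_bp must be >= 0")
  base_gr <- GenomicRanges::reduce(as_granges(hotspots),
                                   ignore.strand = TRUE)
  accepted <- decisions[decisions$accepted, , drop = FALSE]
  panel_gr <- base_gr
  if (nrow(accepted) > 0L) {
    if (is.null(budget_bp)) {
      panel_gr <- GenomicRanges::reduce(c(base_gr, as_granges(accepted)),
                                        ignore.strand = TRUE)
    } else {
      added_bp <- 0L
      for (i in seq_len(nrow(accepted))) { # already sorted by prior desc
        cand_gr <- as_granges(accepted[i, , drop = FALSE])
        new_bp <- sum(IRanges::width(
          GenomicRanges::setdiff(cand_gr, panel_gr, ignore.strand = TRUE)))
        if (added_bp + new_bp > budget_bp) next
        panel_gr <- GenomicRanges::reduce(c(panel_gr, cand_gr),
                                          ignore.strand = TRUE)
        added_bp <- added_bp + new_bp
      }
    }
  }
  panel_gr <- GenomicRanges::sort(panel_gr, ignore.strand = TRUE)
  regions <- from_granges(panel_gr)
  is_hot <- overlaps_any(panel_gr, base_gr)
  regions$provenance <- ifelse(is_hot, "hotspot", "expanded")
  structure(list(regions = regions,
                 total_length_bp = sum(interval_length(regions))),
            class = "mrd_panel")
}

#' @export
print.mrd_panel <- function(x, ...) {
  cat("<mrd_panel> ", nrow(x$regions), " regions, ",
      x$total_length_bp, " bp (",
      sum(x$regions$provenance == "hotspot"), " hotspot / ",
      sum(x$regions$provenance == "expanded"), " expanded)\n", sep = "")
  invisible(x)
}
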