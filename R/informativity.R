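#' Feature informativity rates via a Poisson-Binomial model
#'
#' Raw candidate features are mapped to probabilities by asking: how does
#' this candidate's feature value sit within the distribution of the same
#' feature over the hotspot (seed) regions, which are by construction the
#' "informative instances"? Each instance carries a Bernoulli informativity
#' indicator; the count of informative instances in a candidate's
#' neighborhood then follows a Poisson-Binomial distribution, and the
#' feature informativity rate (FIR) is the upper-tail probability of seeing
#' at least `l` informative instances.
#'
#' @name informativity
NULL

#' Bernoulli informativity probability of one instance
#'
#' Hotspot instances are informative by definition (probability 1). For a
#' candidate, the probability is the Laplace-smoothed empirical CDF of the
#' hotspot feature values at the candidate's value: `(r + 1) / (n_h + 2)`
#' with `r` the number of hotspot values `<=` the candidate's. Smoothing
#' keeps the probability strictly inside (0, 1) so the Poisson-Binomial
#' model never degenerates.
#'
#' @param feature_value candidate's value for one feature.
#' @param hotspot_values the same feature over all hotspot regions.
#' @param is_hotspot is this instance itself a hotspot region?
#' @return probability in (0, 1], vectorized over `feature_value`.
#' @export
estimate_pij <- function(feature_value, hotspot_values, is_hotspot = FALSE) {
  if (is_hotspot) return(rep(1, length(feature_value)))
  n_h <- length(hotspot_values)
  if (n_h == 0L) {
    stop("estimate_pij needs a non-empty hotspot value pool for candidates")
  }
  r <- vapply(feature_value, function(x) sum(hotspot_values <= x), 0)
  (r + 1) / (n_h + 2)
}

#' Poisson-Binomial cumulative distribution function
#'
#' P(N <= l) for N the number of successes among independent Bernoulli
#' trials with heterogeneous probabilities, by the standard O(n^2)
#' convolution recursion.
#'
#' @param probs success probabilities in `[0, 1]`.
#' @param l count, `0 <= l <= length(probs)`.
#' @return P(N <= l).
#' @export
poisson_binomial_cdf <- function(probs, l) {
  if (any(probs < 0) || any(probs > 1)) stop("probs must lie in [0, 1]")
  n <- length(probs)
  if (l < 0 || l > n) stop("l must lie in 0..", n)
  sum(poisson_binomial_pmf(probs)[seq_len(l + 1L)])
}

# Internal: full pmf P(N = 0..n) by convolution.
poisson_binomial_pmf <- function(probs) {
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  pmf
}

#' Feature informativity rate
#'
#' Probability that at least `l` of the instances (the `nis` surrounding
#' hotspot instances, each with probability 1, plus the candidate itself)
#' are informative: `1 - CDF(l - 1)`. With the default `l = nis + 1` and
#' certain surroundings this reduces to the candidate's own probability.
#'
#' @param probs instance probabilities (length `nis + 1`).
#' @param l required informative-instance count; default `length(probs)`.
#' @return probability in `[0, 1]`.
#' @export
feature_informativity_rate <- function(probs, l = length(probs)) {
  if (l == 0L) return(1)
  1 - poisson_binomial_cdf(probs, l - 1L)
}

#' Informativity vector of a candidate region
#'
#' One FIR per feature: the candidate's Bernoulli probability comes from
#' [estimate_pij()] against the hotspot pool for that feature; the `nis`
#' surrounding hotspot instances enter with probability 1.
#'
#' @param feature_values named numeric vector (the candidate's features).
#' @param hotspot_features matrix of hotspot feature vectors (one row per
#'   hotspot region, columns matching `feature_values`).
#' @param nis number of surrounding informative (hotspot) instances.
#' @param is_hotspot treat the candidate itself as a hotspot instance.
#' @param l_override optional fixed `l` instead of the default `nis + 1`.
#' @return numeric vector of FIRs in `[0, 1]`, same names as
#'   `feature_values`.
#' @export
informativity_vector <- function(feature_values, hotspot_features,
                                 nis = 0L, is_hotspot = FALSE,
                                 l_override = NULL) {
  d <- length(feature_values)
  out <- numeric(d)
  l <- if (is.null(l_override)) nis + 1L else l_override
  for (j in seq_len(d)) {
    p_cand <- estimate_pij(feature_values[j], hotspot_features[, j],
                           is_hotspot = is_hotspot)
    probs <- c(rep(1, nis), p_cand)
    out[j] <- feature_informativity_rate(probs, l = min(l, length(probs)))
  }
  names(out) <- names(feature_values)
  out
}

#' Informativity matrix for many candidates
#'
#' @param feature_matrix candidates-by-features numeric matrix.
#' @param hotspot_features hotspot-regions-by-features matrix (the pool).
#' @param nis integer vector of surrounding-hotspot counts per candidate
#'   (recycled).
#' @param is_hotspot logical vector, recycled: rows that are themselves
#'   hotspot regions.
#' @param l_override optional fixed `l`.
#' @return matrix of FIRs, same shape as `feature_matrix`.
#' @export
informativity_matrix <- function(feature_matrix, hotspot_features,
                                 nis = 0L, is_hotspot = FALSE,
                                 l_override = NULL) {
  n <- nrow(feature_matrix)
  nis <- rep_len(nis, n)
  is_hotspot <- rep_len(is_hotspot, n)
  out <- matrix(NA_real_, n, ncol(feature_matrix),
                dimnames = dimnames(feature_matrix))
  for (i in seq_len(n)) {
    out[i, ] <- informativity_vector(feature_matrix[i, ], hotspot_features,
                                     nis = nis[i],
                                     is_hotspot = is_hotspot[i],
                                     l_override = l_override)
  }
  out
}

#' Count surrounding hotspot instances per candidate
#'
#' The neighborhood defaults to the candidate's exon (`mode = "exon"`): the
#' number of hotspot clusters sharing the candidate's exon. With
#' `mode = "flank"`, hotspot clusters within `flank_bp` of the candidate
#' count instead.
#'
#' @param clusters candidate cluster table (with `exon_idx`).
#' @param hotspot_clusters hotspot cluster table (with `exon_idx`).
#' @param mode `"exon"` or `"flank"`.
#' @param flank_bp neighborhood half-width for `mode = "flank"`.
#' @return integer vector of `nis` per candidate row.
#' @export
count_surrounding_hotspots <- function(clusters, hotspot_clusters,
                                       mode = c("exon", "flank"),
                                       flank_bp = 1000L) {
  mode <- match.arg(mode)
  n <- nrow(clusters)
  if (n == 0L || nrow(hotspot_clusters) == 0L) return(integer(n))
  if (mode == "exon") {
    tab <- table(hotspot_clusters$exon_idx)
    counts <- integer(n)
    m <- match(as.character(clusters$exon_idx), names(tab))
    counts[!is.na(m)] <- as.integer(tab[m[!is.na(m)]])
    counts
  } else {
    widened <- clusters
    widened$start <- pmax(1L, clusters$start - as.integer(flank_bp))
    widened$end <- clusters$end + as.integer(flank_bp)
    count_overlaps(as_granges(widened), as_granges(hotspot_clusters))
  }
}
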