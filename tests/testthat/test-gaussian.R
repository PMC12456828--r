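# Build an mrd_gaussian with exact mu/sigma for hand-checked distances.
manual_model <- function(mu, sigma, alpha = 0.05) {
  structure(list(mu = mu, sigma = sigma, chol = chol(sigma),
                 d = length(mu), epsilon = 0, alpha = alpha,
                 chi2_threshold = chi2_critical(alpha, length(mu))),
            class = "mrd_gaussian")
}

test_that("fit_gaussian computes mean and regularized covariance", {
  # identical rows: sample covariance is zero, sigma = eps * I exactly
  X <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 5), nrow = 5)
  model <- fit_gaussian(X, epsilon = 1e-6)
  expect_equal(model$sigma, diag(1e-6, 4))
  expect_equal(model$mu, c(0.2, 0.4, 0.6, 0.8))

  m2 <- fit_gaussian(rbind(c(0, 0), c(2, 2)))
  expect_equal(m2$mu, c(1, 1))

  # n = 3 < d = 4: regularization keeps sigma positive-definite
  set.seed(2)
  X3 <- matrix(runif(12), nrow = 3)
  expect_no_error(chol(fit_gaussian(X3)$sigma))

  expect_error(fit_gaussian(X3[1, , drop = FALSE]), "at least 2")
  X3[1, 1] <- NA
  expect_error(fit_gaussian(X3), "non-finite")
})

test_that("mahalanobis_sq matches hand matrix algebra", {
  model <- manual_model(mu = c(1, 2), sigma = diag(2))
  expect_equal(mahalanobis_sq(c(1, 2), model), 0)
  expect_equal(mahalanobis_sq(c(2, 3), model), 2)          # identity sigma
  model2 <- manual_model(mu = c(0, 0), sigma = diag(c(4, 1)))
  expect_equal(mahalanobis_sq(c(2, 0), model2), 1)          # diag(4, 1)
  expect_error(mahalanobis_sq(c(1, 2, 3), model), "dimension mismatch")
})

test_that("Cholesky solve agrees with the explicit-inverse formula", {
  set.seed(17)
  for (rep in 1:20) {
    A <- matrix(rnorm(16), 4)
    sigma <- crossprod(A) + diag(0.5, 4)
    mu <- rnorm(4)
    model <- manual_model(mu, sigma)
    x <- rnorm(4)
    expect_equal(mahalanobis_sq(x, model),
                 drop(t(x - mu) %*% solve(sigma) %*% (x - mu)),
                 tolerance = 1e-9)
    # independent route: stats::mahalanobis
    expect_equal(mahalanobis_sq(x, model),
                 unname(stats::mahalanobis(matrix(x, 1), mu, sigma)),
                 tolerance = 1e-9)
  }
})

test_that("chi-squared critical values match standard tables", {
  expect_equal(chi2_critical(0.05, 4), 9.4877, tolerance = 1e-3)
  expect_equal(chi2_critical(0.05, 1), 3.8415, tolerance = 1e-3)
  expect_equal(chi2_critical(0.01, 4), 13.2767, tolerance = 1e-3)
  expect_error(chi2_critical(0, 4), "alpha")
  expect_error(chi2_critical(0.05, 0), "d must be")
})

test_that("prior_score decays exponentially in distance", {
  expect_equal(prior_score(0, T = 9.4877), 1.0)
  expect_equal(prior_score(9.4877^2, T = 9.4877), exp(-1))
  expect_gt(prior_score(1, T = 5), prior_score(2, T = 5))
  expect_error(prior_score(1, T = 0), "T must be")
  expect_error(prior_score(-1, T = 1), "d2 must be")
})

test_that("screen_candidates applies the threshold and sorts by prior", {
  set.seed(3)
  X <- matrix(runif(200), ncol = 4)
  model <- fit_gaussian(X)
  cands <- genomic_intervals("chr1", c(100L, 200L, 300L),
                             c(139L, 239L, 339L))
  at_mu <- model$mu
  near <- model$mu + sqrt(diag(model$sigma)) * 0.5
  # far enough that D^2 certainly exceeds the threshold
  far <- model$mu + sqrt(diag(model$sigma)) * 10
  dec <- screen_candidates(model, cands, rbind(at_mu, near, far))
  expect_equal(nrow(dec), 3L)
  expect_equal(dec$prior[1L], 1.0)  # the at-mu candidate ranks first
  expect_true(all(dec$accepted == (dec$d2 <= model$chi2_threshold)))
  expect_false(dec$accepted[dec$d2 == max(dec$d2)])
  expect_true(all(diff(dec$prior) <= 0))
})

test_that("assemble_panel merges regions and honors the budget", {
  hot <- genomic_intervals("chr1", c(1000L, 2000L), c(1099L, 2099L))
  none <- data.frame(chrom = character(), start = integer(),
                     end = integer(), accepted = logical(),
                     prior = numeric())
  panel0 <- assemble_panel(hot, none)
  expect_equal(nrow(panel0$regions), 2L)
  expect_true(all(panel0$regions$provenance == "hotspot"))
  expect_equal(panel0$total_length_bp, 200L)

  dec <- data.frame(chrom = "chr1",
                    start = c(100L, 300L, 500L),
                    end = c(139L, 339L, 539L),
                    prior = c(0.9, 0.8, 0.7),
                    accepted = TRUE)
  # budget admits exactly the top two 40-bp expansions
  panel <- assemble_panel(hot, dec, budget_bp = 80L)
  exp_regions <- panel$regions[panel$regions$provenance == "expanded", ]
  expect_equal(exp_regions$start, c(100L, 300L))

  # adjacent accepted regions merge
  adj <- data.frame(chrom = "chr1", start = c(100L, 140L),
                    end = c(139L, 160L), prior = c(0.9, 0.8),
                    accepted = TRUE)
  merged <- assemble_panel(hot, adj)
  exp_m <- merged$regions[merged$regions$provenance == "expanded", ]
  expect_equal(exp_m$start, 100L)
  expect_equal(exp_m$end, 160L)

  expect_error(assemble_panel(hot, dec, budget_bp = -1), "budget_bp")
})
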