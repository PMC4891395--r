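#' Marginal likelihood of an observed correlation under a prior
#'
#' Integrates the reduced likelihood of the observed sample correlation
#' over a prior on rho: \eqn{m = \int p(r \mid \rho, n)\, \pi(\rho)\, d\rho}
#' on the prior's support. Adaptive quadrature, split at the observed r
#' (and, for a posterior-based prior, at the original study's r) so the
#' sharp likelihood peaks of large-n studies are always resolved.
#'
#' @param summary a [study_summary()].
#' @param prior a [rho_prior].
#' @param rel_tol required relative quadrature accuracy (default 1e-8).
#' @return A list of class `marginal_lik` with `value`, `log_value`, and
#'   the achieved `rel_error`.
#' @export
marginal_likelihood <- function(summary, prior, rel_tol = 1e-8) {
  stopifnot(inherits(summary, "study_summary"), inherits(prior, "rho_prior"))
  support <- prior_support(prior)
  features <- c(summary$r, 0)
  if (prior$family == "posterior_based") {
    features <- c(features, prior$origin$r)
  }
  f <- function(rho) {
    r_density(summary$r, rho, summary$n) * prior_density(prior, rho)
  }
  quadrature_sum(f, support[1], support[2], features, rel_tol)
}

# piecewise adaptive quadrature with interior split points; values are
# summed and the absolute error estimates propagated
quadrature_sum <- function(f, lo, hi, features, rel_tol) {
  cuts <- sort(unique(c(lo, hi,
                        features[features > lo & features < hi])))
  value <- 0
  abs_err <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    piece <- stats::integrate(f, cuts[i], cuts[i + 1L],
                              rel.tol = 1e-11, abs.tol = 0,
                              subdivisions = 1000L, stop.on.error = FALSE)
    if (!piece$message %in% c("OK", "roundoff error was detected")) {
      stop_corbf("corbf_numeric_error",
                 "quadrature failed on (%g, %g): %s",
                 cuts[i], cuts[i + 1L], piece$message)
    }
    value <- value + piece$value
    abs_err <- abs_err + piece$abs.error
  }
  if (value <= 0 || abs_err / value > rel_tol) {
    stop_corbf("corbf_numeric_error",
               "quadrature did not reach the requested tolerance (%g > %g)",
               abs_err / max(value, .Machine$double.xmin), rel_tol)
  }
  structure(list(value = value, log_value = log(value),
                 rel_error = abs_err / value),
            class = "marginal_lik")
}

new_bf_result <- function(log_bf01, numeric_error, alternative, label = "") {
  structure(list(bf01 = exp(log_bf01), bf10 = exp(-log_bf01),
                 log_bf01 = log_bf01, numeric_error = numeric_error,
                 alternative = alternative, label = label),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF01 = %.6g (BF10 = %.6g, log BF01 = %.6g)\n",
              x$bf01, x$bf10, x$log_bf01))
  if (nzchar(x$label)) cat("  test:", x$label, "\n")
  if (inherits(x$alternative, "rho_prior")) {
    cat("  alternative "); print(x$alternative)
  }
  cat(sprintf("  estimated relative numeric error %.2g\n", x$numeric_error))
  invisible(x)
}

bf_from_marginal <- function(summary, prior, label) {
  m <- marginal_likelihood(summary, prior)
  log_num <- r_density(summary$r, 0, summary$n, log = TRUE)
  new_bf_result(log_num - m$log_value, m$rel_error, prior, label)
}

#' Default two-sided Bayes factor BF01
#'
#' Jeffreys's default test of H0: rho = 0 against H1: rho ~ U(-1, 1):
#' \deqn{\mathrm{BF}_{01} = \frac{p(r \mid \rho = 0, n)}
#'   {\int_{-1}^{1} p(r \mid \rho, n)\, \tfrac12\, d\rho}.}
#' Values above 1 favor the absence of a correlation; BF10 = 1/BF01.
#'
#' @param summary a [study_summary()].
#' @return A `bf_result`.
#' @examples
#' bf01(study_summary(480, -0.01))  # strong support for rho = 0
#' @export
bf01 <- function(summary) {
  bf_from_marginal(summary, uniform_prior(),
                   "two-sided default (H1: rho ~ U(-1, 1))")
}

#' One-sided Bayes factor BF0+
#'
#' Sign-restricted test of H0: rho = 0 against H+: rho ~ U(0, 1) (or
#' H-: rho ~ U(-1, 0)), for directional substantive hypotheses. For a
#' symmetric prior the restriction can favor the alternative at most
#' two-fold relative to the two-sided test; when the observed effect goes
#' against the predicted direction the evidence for H0 is amplified.
#'
#' @param summary a [study_summary()].
#' @param direction predicted sign of the correlation.
#' @return A `bf_result`.
#' @examples
#' bf0plus(study_summary(235, -0.06))  # effect opposite to prediction
#' @export
bf0plus <- function(summary, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  bf_from_marginal(summary, one_sided_prior(direction),
                   sprintf("one-sided (H%s: rho ~ U(%s))",
                           if (direction == "positive") "+" else "-",
                           if (direction == "positive") "0, 1" else "-1, 0"))
}

#' Prior sensitivity analysis over the stretched-beta family
#'
#' Recomputes the two-sided Bayes factor with stretched-beta(alpha, alpha)
#' priors of width gamma = 1/alpha, for a grid of widths. gamma = 1
#' reproduces the default uniform-prior analysis; as gamma -> 0 the
#' alternative collapses onto the null and the Bayes factor tends to 1
#' (log BF -> 0).
#'
#' @param summary a [study_summary()].
#' @param gamma strictly increasing vector of prior widths in (0, 1].
#' @return A data frame of class `sensitivity_curve` with columns `gamma`,
#'   `bf01`, `log_bf01`, and the summary as attribute `summary`.
#' @export
bf_sensitivity <- function(summary,
                           gamma = seq(0.005, 1, length.out = 200L)) {
  stopifnot(inherits(summary, "study_summary"))
  if (any(diff(gamma) <= 0)) {
    stop_corbf("corbf_domain_error", "gamma grid must be strictly increasing")
  }
  if (any(gamma <= 0) || any(gamma > 1)) {
    stop_corbf("corbf_domain_error", "gamma values must lie in (0, 1]")
  }
  log_bf <- vapply(gamma, function(g) {
    bf_from_marginal(summary, stretched_beta_prior(g), "")$log_bf01
  }, numeric(1))
  out <- data.frame(gamma = gamma, bf01 = exp(log_bf), log_bf01 = log_bf)
  attr(out, "summary") <- summary
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

#' Interval-null Bayes factor
#'
#' Replaces the point null by a narrow interval, H0': rho ~ U(-c, c), and
#' tests it against the default alternative H1: rho ~ U(-1, 1). For small c
#' the result is virtually identical to the point-null Bayes factor; as
#' c -> 1 the two hypotheses coincide and the Bayes factor tends to 1.
#'
#' @param summary a [study_summary()].
#' @param halfwidth interval half-width c in (0, 1).
#' @return A `bf_result` (bf01 field holds BF of H0' over H1).
#' @export
bf_interval_null <- function(summary, halfwidth = 0.01) {
  stopifnot(inherits(summary, "study_summary"))
  m0 <- marginal_likelihood(summary, interval_prior(halfwidth))
  m1 <- marginal_likelihood(summary, uniform_prior())
  new_bf_result(m0$log_value - m1$log_value, m0$rel_error + m1$rel_error,
                uniform_prior(),
                sprintf("interval null (H0': rho ~ U(-%g, %g)) vs uniform H1",
                        halfwidth, halfwidth))
}

#' Replication Bayes factor BF0r
#'
#' Tests a skeptic's H0: rho = 0 against a proponent's Hr, whose prior on
#' rho is the posterior distribution from an original study (computed under
#' `base`, by default the uniform prior). It asks: is the effect in the
#' replication data similar to what was found before, or absent?
#'
#' @param original [study_summary()] of the original study.
#' @param replication [study_summary()] of the replication attempt.
#' @param base prior updated by the original study; default uniform.
#' @return A `bf_result`.
#' @examples
#' bf_replication(study_summary(41, 0.37), study_summary(210, 0.13))
#' @export
bf_replication <- function(original, replication, base = uniform_prior()) {
  stopifnot(inherits(original, "study_summary"),
            inherits(replication, "study_summary"))
  out <- bf_from_marginal(
    replication, replication_prior(original, base),
    sprintf("replication (Hr: posterior of n = %d, r = %g)",
            original$n, original$r))
  if (out$bf01 > 1e4) {
    warn_corbf("corbf_extreme_bf_warning",
               "BF0r = %.4g: at this magnitude rounding of the input r dominates precision",
               out$bf01)
  }
  out
}

#' Sequential analysis of two studies: the multiplication rule
#'
#' Bayes factors of related studies may only be multiplied when the prior is
#' updated between them: BF(E1, E2) = BF(E1) x BF(E2 | E1), where the second
#' factor integrates the likelihood of E2 over the posterior after E1.
#' Multiplying the two individually computed Bayes factors instead reuses
#' the prior twice and overstates the joint evidence.
#'
#' The joint Bayes factor is defined on the product of the two reduced
#' likelihoods (the studies are independent given a shared rho).
#'
#' @param first,second [study_summary()] objects.
#' @param prior prior on rho shared by the two analyses; default uniform.
#' @return A list of class `sequential_bf` with `bf_first`,
#'   `bf_second_given_first`, `bf_joint` (all `bf_result`), satisfying
#'   `bf_joint = bf_first * bf_second_given_first` up to quadrature error.
#' @export
bf_sequential <- function(first, second, prior = uniform_prior()) {
  stopifnot(inherits(first, "study_summary"),
            inherits(second, "study_summary"))
  bf1 <- bf_from_marginal(first, prior, "first study")
  bf2 <- bf_from_marginal(second, replication_prior(first, base = prior),
                          "second study given the first")
  support <- prior_support(prior)
  f <- function(rho) {
    r_density(first$r, rho, first$n) * r_density(second$r, rho, second$n) *
      prior_density(prior, rho)
  }
  mj <- quadrature_sum(f, support[1], support[2],
                       c(first$r, second$r, 0), rel_tol = 1e-8)
  log_num <- r_density(first$r, 0, first$n, log = TRUE) +
    r_density(second$r, 0, second$n, log = TRUE)
  bfj <- new_bf_result(log_num - mj$log_value, mj$rel_error, prior,
                       "joint analysis of both studies")
  structure(list(bf_first = bf1, bf_second_given_first = bf2,
                 bf_joint = bfj),
            class = "sequential_bf")
}

#' @export
print.sequential_bf <- function(x, ...) {
  cat(sprintf("BF01(E1)        = %.6g\n", x$bf_first$bf01))
  cat(sprintf("BF01(E2 | E1)   = %.6g\n", x$bf_second_given_first$bf01))
  cat(sprintf("BF01(E1, E2)    = %.6g  (= product, up to quadrature error)\n",
              x$bf_joint$bf01))
  invisible(x)
}

#' Update prior model odds by a Bayes factor
#'
#' Posterior odds P(H0 | d)/P(H1 | d) = prior odds x BF01.
#'
#' @param prior_odds positive prior odds P(H0)/P(H1).
#' @param bf a `bf_result` or a positive number (taken as BF01).
#' @return Posterior odds (numeric).
#' @examples
#' update_odds(1 / 9, 9)  # a proponent's odds after BF01 = 9
#' @export
update_odds <- function(prior_odds, bf) {
  if (length(prior_odds) != 1L || !is.finite(prior_odds) || prior_odds <= 0) {
    stop_corbf("corbf_domain_error", "prior odds must be a positive number")
  }
  b <- if (inherits(bf, "bf_result")) bf$bf01 else as.numeric(bf)
  if (!is.finite(b) || b <= 0) {
    stop_corbf("corbf_domain_error", "Bayes factor must be positive")
  }
  prior_odds * b
}
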