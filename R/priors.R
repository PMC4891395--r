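#' Prior distributions on the correlation
#'
#' Every alternative hypothesis in this package is a prior distribution on
#' the population correlation rho over (-1, 1):
#'
#' * `uniform_prior()` — Jeffreys's default two-sided alternative,
#'   rho ~ U(-1, 1);
#' * `stretched_beta_prior(gamma)` — a beta(alpha, alpha) distribution on
#'   (rho + 1)/2 stretched to (-1, 1), with width `gamma = 1/alpha` in
#'   (0, 1]; `gamma = 1` is the uniform prior and `gamma -> 0` collapses
#'   the alternative onto the point null;
#' * `truncate_prior(prior, lo, hi)` — renormalized restriction of any
#'   prior to a sub-interval;
#' * `one_sided_prior()` — rho ~ U(0, 1) (or U(-1, 0)), the sign-restricted
#'   alternative of a directional hypothesis;
#' * `interval_prior(halfwidth)` — rho ~ U(-c, c), a narrow interval null;
#' * `replication_prior(origin)` — the posterior distribution of rho after
#'   the original study, used as the alternative when testing whether a
#'   replication shows "the effect found before" versus no effect.
#'
#' @param gamma prior width in (0, 1]; internally alpha = 1/gamma.
#' @param prior a `rho_prior` to truncate.
#' @param lo,hi truncation bounds, `-1 <= lo < hi <= 1`.
#' @param direction `"positive"` for support (0, 1), `"negative"` for
#'   (-1, 0).
#' @param halfwidth interval-null half-width c in (0, 1).
#' @param origin [study_summary()] of the original study.
#' @param base prior updated by the original study's likelihood; default
#'   uniform.
#' @return An object of class `rho_prior`.
#' @name rho_prior
NULL

new_rho_prior <- function(family, ...) {
  structure(c(list(family = family), list(...)), class = "rho_prior")
}

#' @rdname rho_prior
#' @export
uniform_prior <- function() {
  new_rho_prior("uniform", alpha = 1, lo = -1, hi = 1)
}

#' @rdname rho_prior
#' @export
stretched_beta_prior <- function(gamma = 1) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma <= 0 || gamma > 1) {
    stop_corbf("corbf_domain_error", "gamma must lie in (0, 1]")
  }
  new_rho_prior("stretched_beta", alpha = 1 / gamma, gamma = gamma,
                lo = -1, hi = 1)
}

#' @rdname rho_prior
#' @export
truncate_prior <- function(prior, lo, hi) {
  stopifnot(inherits(prior, "rho_prior"))
  if (!(lo < hi) || lo < -1 || hi > 1) {
    stop_corbf("corbf_domain_error",
               "need -1 <= lo < hi <= 1, got [%g, %g]", lo, hi)
  }
  if (prior$family == "truncated") {
    # collapse nested truncations onto the underlying base
    return(truncate_prior(prior$base, max(lo, prior$lo), min(hi, prior$hi)))
  }
  log_mass <- prior_log_mass(prior, lo, hi)
  if (!is.finite(log_mass) || log_mass < log(1e-12)) {
    stop_corbf("corbf_empty_support",
               "prior has (numerically) no mass on (%g, %g)", lo, hi)
  }
  new_rho_prior("truncated", base = prior, lo = lo, hi = hi,
                log_mass = log_mass)
}

#' @rdname rho_prior
#' @export
one_sided_prior <- function(direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (direction == "positive") {
    truncate_prior(uniform_prior(), 0, 1)
  } else {
    truncate_prior(uniform_prior(), -1, 0)
  }
}

#' @rdname rho_prior
#' @export
interval_prior <- function(halfwidth) {
  if (length(halfwidth) != 1L || !is.finite(halfwidth) ||
      halfwidth <= 0 || halfwidth >= 1) {
    stop_corbf("corbf_domain_error", "halfwidth must lie in (0, 1)")
  }
  truncate_prior(uniform_prior(), -halfwidth, halfwidth)
}

#' @rdname rho_prior
#' @export
replication_prior <- function(origin, base = uniform_prior()) {
  stopifnot(inherits(origin, "study_summary"), inherits(base, "rho_prior"))
  # normalizing constant: marginal likelihood of the original study's r
  # under the base prior, cached with its quadrature error
  m0 <- marginal_likelihood(origin, base)
  new_rho_prior("posterior_based", origin = origin, base = base,
                log_m0 = m0$log_value, m0_rel_error = m0$rel_error,
                lo = prior_support(base)[1], hi = prior_support(base)[2])
}

# prior mass on (lo, hi); closed form where the base is (stretched) beta
prior_log_mass <- function(prior, lo, hi) {
  switch(prior$family,
    uniform = ,
    stretched_beta = {
      a <- prior$alpha
      log(stats::pbeta((hi + 1) / 2, a, a) - stats::pbeta((lo + 1) / 2, a, a))
    },
    posterior_based = {
      f <- function(rho) prior_density(prior, rho)
      log(stats::integrate(f, lo, hi, rel.tol = 1e-10,
                           subdivisions = 500L)$value)
    },
    stop_corbf("corbf_domain_error", "cannot compute mass for family '%s'",
               prior$family)
  )
}

#' Support of a prior on the correlation
#'
#' @param prior a `rho_prior`.
#' @return Numeric `c(lo, hi)`.
#' @export
prior_support <- function(prior) {
  stopifnot(inherits(prior, "rho_prior"))
  c(prior$lo, prior$hi)
}

#' Density of a prior on the correlation
#'
#' Evaluates the normalized prior density at values of rho in (-1, 1).
#' Outside the prior's support the density is 0; support boundaries are
#' treated as limits from inside (so, e.g., the one-sided U(0, 1) prior has
#' density 1 at rho = 0, which is what the Savage-Dickey ratio needs).
#'
#' @param prior a `rho_prior`.
#' @param rho numeric vector in (-1, 1) (endpoints excluded, except that
#'   -1/1 are permitted where the family's density has a finite limit).
#' @param log return log density.
#' @return Numeric vector of densities per unit rho.
#' @examples
#' prior_density(uniform_prior(), 0)              # 0.5
#' prior_density(one_sided_prior(), 0.5)          # 1
#' @export
prior_density <- function(prior, rho, log = FALSE) {
  stopifnot(inherits(prior, "rho_prior"))
  if (any(!is.finite(rho)) || any(abs(rho) > 1)) {
    stop_corbf("corbf_domain_error", "rho must lie in (-1, 1)")
  }
  ld <- switch(prior$family,
    uniform = ifelse(abs(rho) <= 1, log(0.5), -Inf),
    stretched_beta = {
      a <- prior$alpha
      stats::dbeta((rho + 1) / 2, a, a, log = TRUE) - log(2)
    },
    truncated = {
      inside <- rho >= prior$lo & rho <= prior$hi
      out <- rep(-Inf, length(rho))
      if (any(inside)) {
        out[inside] <- prior_density(prior$base, rho[inside], log = TRUE) -
          prior$log_mass
      }
      out
    },
    posterior_based = {
      o <- prior$origin
      # density of rho exactly at the open-interval endpoints is a limit (0
      # for n >= 4 under any bounded base); clamp for the kernel evaluation
      rr <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
      r_density(o$r, rr, o$n, log = TRUE) +
        prior_density(prior$base, rho, log = TRUE) - prior$log_m0
    },
    stop_corbf("corbf_domain_error", "unknown prior family '%s'",
               prior$family)
  )
  if (log) ld else exp(ld)
}

#' @export
print.rho_prior <- function(x, ...) {
  desc <- switch(x$family,
    uniform = "uniform on (-1, 1)",
    stretched_beta = sprintf("stretched beta, gamma = %g (alpha = %g)",
                             x$gamma, x$alpha),
    truncated = sprintf("%s truncated to (%g, %g)",
                        x$base$family, x$lo, x$hi),
    posterior_based = sprintf(
      "posterior of original study (n = %d, r = %g) under %s base",
      x$origin$n, x$origin$r, x$base$family),
    x$family)
  cat("prior on rho:", desc, "\n")
  invisible(x)
}

#' Parse a compact prior specification string
#'
#' Accepted forms: `"uniform"`, `"beta:gamma=0.5"`, `"onesided"` (or
#' `"onesided:negative"`), `"interval:c=0.01"`,
#' `"replication:n=51,r=0.57"`.
#'
#' @param spec character scalar.
#' @return A `rho_prior`.
#' @export
parse_prior <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  family <- parts[1]
  kv <- list()
  if (length(parts) > 1L) {
    for (piece in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
      eq <- strsplit(piece, "=", fixed = TRUE)[[1]]
      if (length(eq) == 2L) {
        kv[[trimws(eq[1])]] <- trimws(eq[2])
      } else {
        kv[[trimws(eq[1])]] <- ""
      }
    }
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.null(kv[[key]]) || is.na(v)) {
      stop_corbf("corbf_usage_error",
                 "prior spec '%s' needs a numeric '%s='", spec, key)
    }
    v
  }
  switch(family,
    uniform = uniform_prior(),
    beta = stretched_beta_prior(gamma = num("gamma")),
    onesided = one_sided_prior(
      if (length(parts) > 1L && parts[2] == "negative") "negative"
      else "positive"),
    interval = interval_prior(num("c")),
    replication = replication_prior(study_summary(num("n"), num("r"))),
    stop_corbf("corbf_usage_error", "unknown prior spec '%s'", spec)
  )
}
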