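#' Study summary: sufficient statistics for all correlation Bayes factors
#'
#' Under the bivariate normal model, once the location and scale nuisance
#' parameters are integrated out every hypothesis test in this package
#' depends on the data only through the number of complete pairs `n` and the
#' sample Pearson correlation `r`. A `study_summary` bundles the two.
#'
#' @param n integer number of complete observation pairs, at least 4.
#' @param r sample Pearson correlation, strictly inside (-1, 1).
#' @param label free-text label carried through to results.
#' @return An object of class `study_summary` with fields `n`, `r`, `label`.
#' @examples
#' study_summary(480, -0.01, "study 2")
#' @export
study_summary <- function(n, r, label = "") {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 4) {
    stop_corbf("corbf_domain_error", "n must be a single integer >= 4")
  }
  if (length(r) != 1L || !is.finite(r) || abs(r) >= 1) {
    stop_corbf("corbf_domain_error", "r must lie strictly inside (-1, 1)")
  }
  if (n < 10) {
    warn_corbf("corbf_small_n_warning",
               "n = %d is small; Bayes factors will be prior-dominated", n)
  }
  structure(list(n = as.integer(n), r = as.numeric(r),
                 label = as.character(label)),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("study summary%s: n = %d, r = %.6g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n, x$r))
  invisible(x)
}

#' Raw paired observations
#'
#' Container for raw (x, y) measurement pairs. Pairs with a missing value in
#' either coordinate are dropped (with a message reporting the count); at
#' least four complete, finite pairs must remain.
#'
#' @param x,y numeric vectors of equal length.
#' @param label free-text label.
#' @return An object of class `bivariate_sample` with fields `x`, `y`,
#'   `label`, `dropped` (number of incomplete pairs removed).
#' @export
bivariate_sample <- function(x, y, label = "") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop_corbf("corbf_domain_error", "x and y must have the same length")
  }
  keep <- !(is.na(x) | is.na(y))
  dropped <- sum(!keep)
  x <- x[keep]
  y <- y[keep]
  if (dropped > 0) {
    message(sprintf("dropped %d incomplete pair(s)", dropped))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_corbf("corbf_domain_error", "non-finite values in paired data")
  }
  if (length(x) < 4) {
    stop_corbf("corbf_insufficient_data",
               "need at least 4 complete pairs, got %d", length(x))
  }
  structure(list(x = x, y = y, label = as.character(label),
                 dropped = dropped),
            class = "bivariate_sample")
}

#' Sample Pearson correlation of a bivariate sample
#'
#' Reduces raw paired observations to the sufficient summary (n, r). Data
#' with zero variance in either coordinate, or a perfect linear relation
#' (|r| = 1), are rejected: the reduced likelihood and every Bayes factor
#' built on it degenerate there.
#'
#' @param sample a [bivariate_sample()], or a two-column data frame / matrix.
#' @param label optional label for the resulting summary (defaults to the
#'   sample's label).
#' @return A [study_summary()].
#' @examples
#' pearson_summary(bivariate_sample(c(1, 2, 3, 4), c(2, 1, 4, 3)))  # r = 0.6
#' @export
pearson_summary <- function(sample, label = NULL) {
  if (is.data.frame(sample) || is.matrix(sample)) {
    if (ncol(sample) < 2) {
      stop_corbf("corbf_domain_error", "need two columns of paired data")
    }
    sample <- bivariate_sample(sample[[1]], sample[[2]])
  }
  if (!inherits(sample, "bivariate_sample")) {
    stop_corbf("corbf_domain_error", "not a bivariate sample")
  }
  if (stats::sd(sample$x) == 0 || stats::sd(sample$y) == 0) {
    stop_corbf("corbf_degenerate_data",
               "zero variance in a coordinate; r is undefined")
  }
  r <- stats::cor(sample$x, sample$y)
  if (abs(r) >= 1 - 1e-12) {
    stop_corbf("corbf_degenerate_data",
               "|r| = 1 (perfect linear relation); downstream tests require |r| < 1")
  }
  study_summary(length(sample$x), r,
                label = if (is.null(label)) sample$label else label)
}

#' Reduced likelihood: exact sampling density of the Pearson correlation
#'
#' Density of the sample correlation r for `n` bivariate-normal pairs with
#' population correlation `rho`, the location and scale parameters having
#' been removed. Evaluated in log space via the Gauss hypergeometric form
#' \deqn{p(r \mid \rho, n) = \frac{(n-2)\,\Gamma(n-1)}{\sqrt{2\pi}\,
#'   \Gamma(n-\tfrac12)} (1-\rho^2)^{\frac{n-1}{2}} (1-r^2)^{\frac{n-4}{2}}
#'   (1-\rho r)^{\frac{3-2n}{2}}
#'   \,{}_2F_1\!\left(\tfrac12,\tfrac12;n-\tfrac12;\tfrac{1+\rho r}{2}\right).}
#' The hypergeometric factor is a positive-term series with ratio bounded by
#' its argument, so the evaluation involves no cancellation.
#'
#' `method = "jeffreys"` gives the classical large-n ratio approximation
#' \eqn{(1-\rho^2)^{(n-1)/2} (1-\rho r)^{(3-2n)/2}}, anchored so it matches
#' the exact density at \eqn{\rho = 0}; it is provided for cross-checking
#' only and is not normalized in r.
#'
#' @param r sample correlation value(s) in (-1, 1).
#' @param rho population correlation value(s) in (-1, 1); `r` and `rho` are
#'   recycled to a common length.
#' @param n integer sample size, at least 4.
#' @param log return the log density.
#' @param method `"exact"` (default) or `"jeffreys"`.
#' @return Numeric vector of (log) densities per unit r.
#' @examples
#' r_density(0.3, 0, 20)
#' integrate(r_density, -1, 1, rho = 0.3, n = 20)  # integrates to 1
#' @export
r_density <- function(r, rho, n, log = FALSE,
                      method = c("exact", "jeffreys")) {
  method <- match.arg(method)
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 4) {
    stop_corbf("corbf_domain_error", "n must be a single integer >= 4")
  }
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop_corbf("corbf_domain_error", "r must lie strictly inside (-1, 1)")
  }
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    stop_corbf("corbf_domain_error", "rho must lie strictly inside (-1, 1)")
  }
  m <- max(length(r), length(rho))
  r <- rep_len(r, m)
  rho <- rep_len(rho, m)
  lconst <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5)
  lnull <- lconst + (n - 4) / 2 * log1p(-r^2) +
    log(hyp2f1_half(n - 0.5, rep_len(0.5, m)))
  ld <- if (method == "exact") {
    lconst + (n - 1) / 2 * log1p(-rho^2) + (n - 4) / 2 * log1p(-r^2) -
      (n - 1.5) * log1p(-rho * r) +
      log(hyp2f1_half(n - 0.5, (1 + rho * r) / 2))
  } else {
    # ratio approximation, matched to the exact density at rho = 0
    lnull + (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r)
  }
  if (log) ld else exp(ld)
}

#' Classical two-sided p value for a correlation
#'
#' Convenience companion: the exact p value under rho = 0, via the
#' t-transform `t = r sqrt((n-2)/(1-r^2))` with n - 2 degrees of freedom.
#'
#' @param summary a [study_summary()].
#' @return p value in (0, 1].
#' @examples
#' classical_p(study_summary(494, 0.10))  # ~ 0.03
#' @export
classical_p <- function(summary) {
  stopifnot(inherits(summary, "study_summary"))
  tt <- summary$r * sqrt((summary$n - 2) / (1 - summary$r^2))
  2 * stats::pt(-abs(tt), df = summary$n - 2)
}

#' Read paired data from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the first line),
#' with or without a header row, selects two numeric columns by name or
#' position, and returns a [bivariate_sample()]. Empty fields and "NA" are
#' treated as missing; incomplete pairs are dropped with a message.
#'
#' @param file path to a delimited text file.
#' @param x,y column names (character) or positions (numeric); default the
#'   first two columns.
#' @param label label for the sample (defaults to the file name).
#' @return A [bivariate_sample()].
#' @export
read_pairs <- function(file, x = 1, y = 2, label = basename(file)) {
  if (!file.exists(file)) {
    stop_corbf("corbf_io_error", "cannot read file '%s'", file)
  }
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))) &
                  nzchar(trimws(fields)) & fields != "NA")
  dat <- utils::read.table(file, sep = sep, header = header,
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE)
  pick <- function(col, which) {
    if (is.character(col)) {
      if (!col %in% names(dat)) {
        stop_corbf("corbf_io_error", "column '%s' (%s) not found in '%s'",
                   col, which, file)
      }
      dat[[col]]
    } else {
      if (col < 1 || col > ncol(dat)) {
        stop_corbf("corbf_io_error", "column %d (%s) out of range in '%s'",
                   col, which, file)
      }
      dat[[col]]
    }
  }
  xv <- pick(x, "x")
  yv <- pick(y, "y")
  if (!is.numeric(xv) || !is.numeric(yv)) {
    stop_corbf("corbf_io_error", "selected columns are not numeric in '%s'",
               file)
  }
  bivariate_sample(xv, yv, label = label)
}
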