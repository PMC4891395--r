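# Gauss hypergeometric series specialized to the arguments the reduced
# likelihood of r needs: 2F1(1/2, 1/2; c; z) with c = n - 1/2 >= 3.5 and
# z = (1 + rho*r)/2 in [0, 1). All series terms are positive, the term
# ratio is bounded by z, so the sum converges geometrically with no
# cancellation and stays O(1) for every admissible (n, z).
hyp2f1_half <- function(cc, z, tol = 1e-15, max_terms = 50000L) {
  if (cc <= 1) stop("hypergeometric parameter c must exceed 1")
  if (any(z < 0) || any(z >= 1)) {
    stop_corbf("corbf_domain_error", "hypergeometric argument must lie in [0, 1)")
  }
  term <- rep.int(1, length(z))
  total <- rep.int(1, length(z))
  active <- rep.int(TRUE, length(z))
  k <- 0L
  while (any(active)) {
    fac <- (0.5 + k)^2 / ((cc + k) * (k + 1))
    term[active] <- term[active] * fac * z[active]
    total[active] <- total[active] + term[active]
    active <- active & (term > tol * total)
    k <- k + 1L
    if (k >= max_terms) {
      stop_corbf("corbf_numeric_error", sprintf(
        "hypergeometric series did not converge in %d terms (max z = %g)",
        max_terms, max(z)))
    }
  }
  total
}

# classed conditions used throughout the package
stop_corbf <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "corbf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_corbf <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "corbf_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
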