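#' Raised-cosine temporal basis
#'
#' Log-warped raised-cosine "bump" functions used to represent temporal
#' filters compactly. With warped time \code{u(t) = log(t + psi)} (t in ms),
#' the K bump centers are equally spaced in u between \code{u(0)} and
#' \code{u(span_ms - 1)}; \code{gamma} is the center spacing in u. The k-th
#' basis vector is \code{b_k(t) = (cos(q_k(t)) + 1)/2} with
#' \code{q_k(t) = (u(t) - u(phi_k)) * pi / (2*gamma)}, set to zero wherever
#' \code{|q_k| > pi}. Small \code{psi} concentrates resolution near lag 0;
#' very large \code{psi} degenerates to linear spacing.
#'
#' @param n_basis number of basis vectors (>= 2).
#' @param span_ms filter span in ms (>= 2); basis evaluated at integer lags
#'   0, 1, ..., span_ms - 1 (bin left edges).
#' @param psi warp constant (> 0); 10 for retinal, 8 for LGN components by
#'   convention here.
#' @return an object of class \code{raised_cosine_basis}: fields
#'   \code{n_basis}, \code{span_ms}, \code{psi}, \code{centers} (time-domain
#'   bump centers, ms), \code{centers_u} (warped), \code{gamma} and
#'   \code{matrix} (span_ms x n_basis).
#' @export
make_basis <- function(n_basis, span_ms, psi) {
  if (n_basis < 2L) stop("n_basis must be >= 2")
  if (span_ms < 2L) stop("span_ms must be >= 2")
  if (psi <= 0) stop("psi must be > 0")
  u <- function(t) log(t + psi)
  t <- seq(0, span_ms - 1)
  cu <- seq(u(0), u(span_ms - 1), length.out = n_basis)
  gamma <- cu[2L] - cu[1L]
  if (gamma <= 0) stop("degenerate basis: gamma = 0 (too many basis vectors for span)")
  q <- outer(u(t), cu, `-`) * pi / (2 * gamma)
  B <- (cos(pmin(pmax(q, -pi), pi)) + 1) / 2
  B[abs(q) > pi] <- 0
  structure(list(n_basis = n_basis, span_ms = span_ms, psi = psi,
                 centers = exp(cu) - psi, centers_u = cu, gamma = gamma,
                 matrix = B),
            class = "raised_cosine_basis")
}

#' @export
print.raised_cosine_basis <- function(x, ...) {
  cat(sprintf("<raised_cosine_basis: %d bumps over %d ms, psi = %g, gamma = %.4f>\n",
              x$n_basis, x$span_ms, x$psi, x$gamma))
  invisible(x)
}

#' Transform basis-domain coefficients to a time-domain filter
#'
#' \code{theta_time = B \%*\% theta_star} per component.
#'
#' @param theta_star coefficient vector of length \code{n_basis}.
#' @param basis a \code{raised_cosine_basis}.
#' @return numeric filter over 1-ms lags (length \code{span_ms}).
#' @export
basis_to_time <- function(theta_star, basis) {
  stopifnot(inherits(basis, "raised_cosine_basis"))
  if (length(theta_star) != basis$n_basis) {
    stop(sprintf("dimension mismatch: %d coefficients for %d basis vectors",
                 length(theta_star), basis$n_basis))
  }
  drop(basis$matrix %*% theta_star)
}
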