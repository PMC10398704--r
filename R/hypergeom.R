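# Closed-form angular kernel of the cylinder-cylinder surface integral.
#
# With rho^2 = alpha + beta sin^2(theta/2), where
# alpha = (b1 - b2)^2 + (z1 - z2 - Z)^2 and beta = 4 b1 b2, the integral of
# rho^(-2n) over one angle is
#
#   J_n = int_0^{2pi} (alpha + beta sin^2(theta/2))^(-n) dtheta
#       = 2 pi alpha^(-n) 2F1(n, 1/2; 1; -beta/alpha)
#       = 2 pi (alpha + beta)^(-n) 2F1(n, 1/2; 1; beta/(alpha + beta)),
#
# the two forms being related by the Pfaff transformation.  The second form
# keeps the argument in [0, 1) and is the one evaluated here.

# 2F1(n, 1/2; 1; x) for integer n >= 1 and x in [0, 1), vectorised in x.
#
# For these parameters the Gauss function terminates under the z -> 1 - z
# linear transformation: with y = 1 - x,
#   2F1(n, 1/2; 1; x) = [Gamma(n - 1/2) / (Gamma(n) Gamma(1/2))] *
#                       y^(1/2 - n) * 2F1(1 - n, 1/2; 3/2 - n; y)
# (the companion term of the transformation vanishes because Gamma(1 - n) has
# a pole), and 2F1(1 - n, 1/2; 3/2 - n; y) is a degree-(n - 1) polynomial
# whose coefficients are all positive.  The evaluation is therefore exact to
# rounding and free of cancellation over the whole of [0, 1), including the
# near-contact regime x -> 1 where the series form converges slowly.
hyp2f1_n_half <- function(x, n) {
  if (any(x < 0 | x >= 1)) stop("argument must lie in [0, 1)")
  n <- as.integer(n)
  stopifnot(n >= 1)
  y <- 1 - x
  coef <- numeric(n)
  coef[1] <- 1
  if (n > 1) {
    k <- seq_len(n - 1)
    # ratio of consecutive coefficients of 2F1(1-n, 1/2; 3/2-n; y)
    ratio <- (1 - n + k - 1) * (0.5 + k - 1) / ((1.5 - n + k - 1) * k)
    coef[-1] <- cumprod(ratio)
  }
  poly <- rep(coef[n], length(y))
  if (n > 1) for (j in (n - 1):1) poly <- poly * y + coef[j]
  pref <- gamma(n - 0.5) / (gamma(n) * gamma(0.5))
  pref * y^(0.5 - n) * poly
}

#' Angular kernel of the cylinder-cylinder potential
#'
#' Closed hypergeometric form of the one-angle integral
#' \deqn{J_n(\alpha,\beta) = \int_0^{2\pi} (\alpha + \beta\sin^2(\theta/2))^{-n}\, d\theta
#'   = 2\pi(\alpha+\beta)^{-n}\, {}_2F_1\!\left(n, \tfrac12; 1; \tfrac{\beta}{\alpha+\beta}\right),}
#' where \eqn{\alpha = (b_1-b_2)^2 + (z_1-z_2-Z)^2} is the squared
#' minimum-gap distance of two surface rings and \eqn{\beta = 4 b_1 b_2}.
#' This removes both angular dimensions of the surface-surface integral
#' (one angle integrates out trivially because the integrand depends only on
#' the angle difference).
#'
#' @param alpha Squared gap parameter in A^2 (> 0); vectorised.
#' @param beta Ring-coupling parameter `4 b1 b2` in A^2 (>= 0).
#' @param n Inverse-power index: 3 (attractive) or 6 (repulsive).
#' @return Kernel values in A^(-2n); same length as `alpha`.
#' @export
#' @examples
#' kernel_j(25, 16, 3)
#' # beta = 0 collapses the hypergeometric factor to 1:
#' kernel_j(25, 0, 3) == 2 * pi * 25^-3
kernel_j <- function(alpha, beta, n) {
  if (!n %in% c(3L, 6L)) stop("'n' must be 3 or 6")
  if (any(alpha <= 0)) stop("'alpha' must be positive (surfaces in contact)")
  if (any(beta < 0)) stop("'beta' must be non-negative")
  ab <- alpha + beta
  2 * pi * ab^(-n) * hyp2f1_n_half(beta / ab, n)
}
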