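#' Construct Monod kinetics parameters
#'
#' @param mu_max maximum specific growth rate (day^-1), > 0.
#' @param Ks half-saturation constant (uM), > 0.
#' @return a [MonodParams-class] object.
#' @examples
#' monodGrowth(3, monodParams(mu_max = 1.2, Ks = 3))
#' @export
monodParams <- function(mu_max, Ks) new("MonodParams", mu_max = mu_max, Ks = Ks)

#' Monod growth rate
#'
#' The classical saturating relation
#' \eqn{\mu = \mu_{max} S / (K_s + S)}: strictly increasing and concave in
#' the substrate concentration, approaching \eqn{\mu_{max}} at saturation
#' and equal to \eqn{\mu_{max}/2} at \eqn{S = K_s}.
#'
#' @param S substrate (nitrate) concentration(s) (uM), >= 0; vectorized.
#' @param p a [MonodParams-class] object.
#' @return growth rate(s) in [0, mu_max) (day^-1).
#' @export
monodGrowth <- function(S, p) {
  stopifnot(is(p, "MonodParams"))
  if (any(!is.finite(S)) || any(S < 0))
    stop("substrate concentration must be finite and >= 0", call. = FALSE)
  p@mu_max * S / (p@Ks + S)
}
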