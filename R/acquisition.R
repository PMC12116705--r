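# Acquisition arithmetic: effective NUS sparsity under spectral-width
# oversampling, and scalar-coupling transfer delays.

#' Effective non-uniform-sampling sparsity
#'
#' When indirect-dimension spectral widths are set wider than the range of
#' the observed signals, the Nyquist grid grows by the product of the
#' per-dimension oversampling factors, and the sparsity relative to the
#' signal-matched grid grows by the same product:
#' \code{effective = nominal * prod(oversampling)}. For example, a nominal
#' sparsity of 0.55\% with two-fold oversampling in three indirect
#' dimensions is an effective sparsity of 0.55\% x 2^3 = 4.4\%.
#'
#' @param nominal nominal NUS sparsity as a fraction in (0, 1].
#' @param oversampling per-dimension oversampling factors (each >= 1); its
#'   length is the number of indirect dimensions.
#' @return list with \code{effective} (fraction) and \code{per_dim}
#'   (\code{effective^(1/n)}, the equivalent per-dimension sparsity).
#' @examples
#' effective_sparsity(0.0055, c(2, 2, 2))$effective  # 0.044
#' @export
effective_sparsity <- function(nominal, oversampling = c(2, 2, 2)) {
  if (nominal <= 0 || nominal > 1) stop("nominal must be in (0, 1]")
  if (any(oversampling < 1)) stop("oversampling factors must be >= 1")
  eff <- nominal * prod(oversampling)
  list(effective = eff, per_dim = eff^(1 / length(oversampling)))
}

#' Scalar-coupling transfer delay
#'
#' INEPT/COSY transfer durations: \code{1/(2J)} ("half") for an
#' out(wards) transfer, \code{1/J} ("full") for a constant-time period
#' spanning a complete coupling evolution.
#'
#' @param J coupling constant in Hz (> 0).
#' @param kind "half" or "full".
#' @return delay in seconds.
#' @examples
#' transfer_delay(125, "half") * 1e3   # 4 ms (1J_HC)
#' transfer_delay(35, "full") * 1e3    # ~28.6 ms (1J_CC)
#' @export
transfer_delay <- function(J, kind = c("half", "full")) {
  kind <- match.arg(kind)
  if (any(J <= 0)) stop("J must be positive")
  if (kind == "half") 1 / (2 * J) else 1 / J
}
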