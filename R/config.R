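#' Bundle run-wide analysis settings
#'
#' Collects the tolerances, PRE parameters, evidence weights and cutoffs
#' shared across an assignment run, validating them once. Evidence weights
#' are normalized to sum to 1.
#'
#' @param tol_H,tol_C peak-matching tolerances (ppm, > 0).
#' @param noe_cutoff expected-contact distance cutoff (\AA).
#' @param weights evidence weights \code{c(noe=, shift=, pre=)}.
#' @param threshold,margin acceptance threshold and runner-up margin for
#'   \code{\link{propagate_assignments}}.
#' @param pre_params a \code{\link{pre_parameters}} object.
#' @param seed integer seed recorded for reproducibility.
#' @return object of class \code{run_config} (a named list).
#' @export
run_config <- function(tol_H = 0.02, tol_C = 0.2, noe_cutoff = 8,
                       weights = c(noe = 0.5, shift = 0.3, pre = 0.2),
                       threshold = 0.4, margin = 0.1,
                       pre_params = pre_parameters(), seed = 1L) {
  if (tol_H <= 0 || tol_C <= 0) stop("tolerances must be positive")
  if (noe_cutoff <= 0) stop("noe_cutoff must be positive")
  if (!all(c("noe", "shift", "pre") %in% names(weights)))
    stop("weights must be named noe, shift, pre")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  structure(list(tol_H = tol_H, tol_C = tol_C, noe_cutoff = noe_cutoff,
                 weights = weights / sum(weights), threshold = threshold,
                 margin = margin, pre_params = pre_params,
                 seed = as.integer(seed)),
            class = "run_config")
}
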