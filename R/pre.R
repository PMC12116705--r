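#' Physical constants for PRE calculations
#'
#' Bundle of the physical constants entering the Solomon-Bloembergen
#' prefactor \code{kappa_H}: the \eqn{^1}H and \eqn{^{13}}C gyromagnetic
#' ratios, the electron g-factor, the Bohr magneton, the vacuum permeability
#' and the electron spin quantum number.
#'
#' The electron g-factor defaults to exactly 2, the value conventionally
#' used in PRE analysis of nitroxide spin labels and the one consistent with
#' the prefactor \eqn{\kappa_H = 1.2311 \times 10^{16}} \AA\eqn{^6}s\eqn{^{-2}}
#' quoted for S = 1/2. The CODATA free-electron value (2.00231930436) may be
#' supplied instead, at the cost of a ~0.2% shift in all predicted rates.
#'
#' @param gamma_H \eqn{^1}H gyromagnetic ratio (rad s\eqn{^{-1}} T\eqn{^{-1}}).
#' @param gamma_C \eqn{^{13}}C gyromagnetic ratio (rad s\eqn{^{-1}} T\eqn{^{-1}}).
#' @param g_e electron g-factor (dimensionless).
#' @param beta Bohr magneton (J T\eqn{^{-1}}).
#' @param mu_0 vacuum permeability (T m A\eqn{^{-1}}).
#' @param S_e electron spin quantum number (1/2 for a nitroxide radical).
#' @return An object of class \code{pre_constants} (a named list).
#' @examples
#' const <- physical_constants()
#' kappa_H(const) # ~1.2311e16 A^6 s^-2
#' @export
physical_constants <- function(gamma_H = 2.6752218744e8,
                               gamma_C = 6.728284e7,
                               g_e = 2,
                               beta = 9.2740100783e-24,
                               mu_0 = 4 * pi * 1e-7,
                               S_e = 0.5) {
  vals <- c(gamma_H = gamma_H, gamma_C = gamma_C, g_e = g_e,
            beta = beta, mu_0 = mu_0, S_e = S_e)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be positive and finite")
  structure(as.list(vals), class = "pre_constants")
}

#' PRE model parameters
#'
#' Parameters of the simplified Solomon-Bloembergen / HMQC intensity-ratio
#' model: electron-nucleus order parameter and correlation time, the
#' spectrometer frequency (from which the \eqn{^1}H Larmor frequency
#' \eqn{\omega_0} is derived), the total fixed HMQC delay, diamagnetic
#' relaxation rates and processing line-broadening.
#'
#' @param S2 squared order parameter of the electron-nucleus vector,
#'   dimensionless in (0, 1].
#' @param tau1 effective correlation time (s).
#' @param spectrometer_freq spectrometer \eqn{^1}H frequency (Hz).
#' @param Delta total duration of the fixed delays in the HMQC sequence (s).
#' @param R2_dia_MQ diamagnetic \eqn{^1}H-\eqn{^{13}}C multiple-quantum
#'   relaxation rate (s\eqn{^{-1}}).
#' @param R2_dia_HSQ diamagnetic \eqn{^1}H single-quantum relaxation rate
#'   (s\eqn{^{-1}}).
#' @param LB_F1,LB_F2 exponential line-broadening in the indirect and direct
#'   dimensions (Hz).
#' @param constants a \code{\link{physical_constants}} object.
#' @return An object of class \code{pre_parameters} with derived fields
#'   \code{omega0} (rad s\eqn{^{-1}}) and \code{mq_factor}
#'   \eqn{= 1 + (\gamma_C/\gamma_H)^2}.
#' @examples
#' p <- pre_parameters()
#' round(p$mq_factor, 3) # 1.063
#' @export
pre_parameters <- function(S2 = 0.8, tau1 = 20e-9,
                           spectrometer_freq = 850e6,
                           Delta = 7.7e-3,
                           R2_dia_MQ = 40, R2_dia_HSQ = 40,
                           LB_F1 = 5, LB_F2 = 5,
                           constants = physical_constants()) {
  if (!inherits(constants, "pre_constants"))
    stop("'constants' must come from physical_constants()")
  if (S2 <= 0 || S2 > 1) stop("S2 must lie in (0, 1]")
  pos <- c(tau1 = tau1, spectrometer_freq = spectrometer_freq, Delta = Delta,
           R2_dia_MQ = R2_dia_MQ, R2_dia_HSQ = R2_dia_HSQ,
           LB_F1 = LB_F1, LB_F2 = LB_F2)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all PRE parameters must be positive and finite")
  out <- list(S2 = S2, tau1 = tau1, spectrometer_freq = spectrometer_freq,
              Delta = Delta, R2_dia_MQ = R2_dia_MQ, R2_dia_HSQ = R2_dia_HSQ,
              LB_F1 = LB_F1, LB_F2 = LB_F2,
              omega0 = 2 * pi * spectrometer_freq,
              mq_factor = 1 + (constants$gamma_C / constants$gamma_H)^2,
              constants = constants)
  structure(out, class = "pre_parameters")
}

#' Solomon-Bloembergen prefactor kappa_H
#'
#' \deqn{\kappa_H = (\gamma_H g_e \beta)^2 (\mu_0/4\pi)^2 S(S+1)/15}
#'
#' The product is formed in SI units (m\eqn{^6} s\eqn{^{-2}}) and converted
#' to \AA\eqn{^6} s\eqn{^{-2}} by the factor \eqn{(10^{10})^6 = 10^{60}};
#' this is the only place in the package where that unit conversion occurs,
#' so that all distances downstream are plain \AA{}ngstr\"om values.
#'
#' @param constants a \code{\link{physical_constants}} object.
#' @return \eqn{\kappa_H} in \AA\eqn{^6} s\eqn{^{-2}}.
#' @export
kappa_H <- function(constants = physical_constants()) {
  if (!inherits(constants, "pre_constants"))
    stop("'constants' must come from physical_constants()")
  S <- constants$S_e
  si <- (constants$gamma_H * constants$g_e * constants$beta)^2 *
    (constants$mu_0 / (4 * pi))^2 * (S * (S + 1) / 15)
  si * 1e60
}

#' Transverse 1H PRE rate from the simplified Solomon-Bloembergen equation
#'
#' \deqn{\Gamma_2^H = \frac{\kappa_H}{r_{eN}^6} S^2 \tau_1
#'   \left(4 + \frac{3}{1 + \omega_0^2 \tau_1^2}\right)}
#'
#' @param r_eN electron to methyl-proton distance(s) in \AA{} (vectorized).
#' @param params a \code{\link{pre_parameters}} object.
#' @return \eqn{\Gamma_2^H} in s\eqn{^{-1}}, same length as \code{r_eN}.
#' @export
gamma2_H <- function(r_eN, params = pre_parameters()) {
  if (any(!is.finite(r_eN)) || any(r_eN <= 0))
    stop("r_eN must be positive and finite")
  spec <- 4 + 3 / (1 + params$omega0^2 * params$tau1^2)
  kappa_H(params$constants) / r_eN^6 * params$S2 * params$tau1 * spec
}

#' Multiple-quantum PRE rate
#'
#' Scales the single-quantum \eqn{^1}H PRE by
#' \eqn{1 + (\gamma_C/\gamma_H)^2 \approx 1.063} to obtain the PRE of the
#' \eqn{^1}H-\eqn{^{13}}C multiple-quantum coherence observed in HMQC.
#'
#' @param g2H \eqn{\Gamma_2^H} in s\eqn{^{-1}} (vectorized, non-negative).
#' @param params a \code{\link{pre_parameters}} object.
#' @return \eqn{\Gamma_2^{HC-MQ}} in s\eqn{^{-1}}.
#' @export
gamma2_MQ <- function(g2H, params = pre_parameters()) {
  if (any(g2H < 0)) stop("gamma2_H must be non-negative")
  params$mq_factor * g2H
}

#' Predicted paramagnetic/diamagnetic HMQC intensity ratio
#'
#' \deqn{\frac{I_{para}}{I_{dia}} = e^{-\Gamma_2^H \Delta}
#'   \frac{(R_2^{MQ} + \pi LB_{F1})(R_2^{HSQ} + \pi LB_{F2})}
#'        {(R_2^{MQ} + \pi LB_{F1} + \Gamma_2^{MQ})
#'         (R_2^{HSQ} + \pi LB_{F2} + \Gamma_2^H)}}
#'
#' Equals 1 exactly at \eqn{\Gamma_2^H = 0} and decreases strictly
#' monotonically towards 0.
#'
#' @param g2H \eqn{\Gamma_2^H} in s\eqn{^{-1}} (vectorized, non-negative).
#' @param params a \code{\link{pre_parameters}} object.
#' @return intensity ratio(s) in (0, 1].
#' @export
intensity_ratio <- function(g2H, params = pre_parameters()) {
  if (any(g2H < 0)) stop("gamma2_H must be non-negative")
  g2mq <- gamma2_MQ(g2H, params)
  a <- params$R2_dia_MQ + pi * params$LB_F1
  b <- params$R2_dia_HSQ + pi * params$LB_F2
  exp(-g2H * params$Delta) * (a * b) / ((a + g2mq) * (b + g2H))
}

#' Place the unpaired electron of a spin label
#'
#' Returns a spin-label site whose electron coordinate is either given
#' explicitly or constructed by extending the C-alpha to C-beta bond vector
#' of the attachment residue by a fixed offset, a single-point stand-in for
#' model-built nitroxide tags (the unpaired electron taken to sit on the
#' nitroxide nitrogen).
#'
#' @param structure an \code{nmr_structure} (only needed for
#'   \code{mode = "cb_offset"}).
#' @param chain chain identifier of the attachment residue.
#' @param resno residue number of the attachment residue.
#' @param mode \code{"cb_offset"} (default) or \code{"explicit"}.
#' @param coord electron coordinate (length-3, \AA) for
#'   \code{mode = "explicit"}.
#' @param offset extension beyond C-beta along the CA->CB direction (\AA).
#' @param label free-form site label (e.g. the mutant name).
#' @return An object of class \code{spin_label_site}: list with
#'   \code{electron_coord}, \code{attachment}, \code{mode}, \code{label}.
#' @export
place_electron <- function(structure = NULL, chain = "A", resno = NULL,
                           mode = c("cb_offset", "explicit"), coord = NULL,
                           offset = 7, label = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    if (is.null(coord) || length(coord) != 3 || any(!is.finite(coord)))
      stop("mode = 'explicit' requires a finite length-3 'coord'")
    electron <- as.numeric(coord)
    attachment <- if (is.null(resno)) NULL else list(chain = chain, resno = resno)
  } else {
    if (is.null(structure) || is.null(resno))
      stop("mode = 'cb_offset' requires 'structure' and 'resno'")
    atoms <- structure$atoms
    sel <- atoms$chain == chain & atoms$resno == resno
    if (!any(sel)) stop("attachment residue not found: ", chain, "/", resno)
    res <- atoms[sel, , drop = FALSE]
    ca <- res[res$atom == "CA", , drop = FALSE]
    cb <- res[res$atom == "CB", , drop = FALSE]
    if (nrow(cb) == 0)
      stop("attachment residue ", resno, " has no CB atom (Gly?)")
    if (nrow(ca) == 0) stop("attachment residue ", resno, " has no CA atom")
    v <- c(cb$x[1] - ca$x[1], cb$y[1] - ca$y[1], cb$z[1] - ca$z[1])
    u <- v / sqrt(sum(v^2))
    electron <- c(cb$x[1], cb$y[1], cb$z[1]) + offset * u
    attachment <- list(chain = chain, resno = resno)
  }
  structure(list(electron_coord = electron, attachment = attachment,
                 mode = mode, label = label),
            class = "spin_label_site")
}

#' Predict a PRE intensity-ratio profile for a set of methyls
#'
#' Composes the electron-methyl distance, \code{\link{gamma2_H}},
#' \code{\link{gamma2_MQ}} and \code{\link{intensity_ratio}} per methyl.
#' Distances are measured from the electron to each methyl's pseudo-atom
#' (the averaged position of the three methyl protons, or the methyl carbon
#' when protons are absent; see \code{\link{extract_methyls}}).
#'
#' @param methyls a methyl table from \code{\link{extract_methyls}} or
#'   \code{\link{generate_constellation}}.
#' @param site a \code{\link{place_electron}} site.
#' @param params a \code{\link{pre_parameters}} object.
#' @return data.frame with columns \code{methyl_id}, \code{r_eN},
#'   \code{gamma2_H}, \code{gamma2_MQ}, \code{ratio}.
#' @export
predict_pre_profile <- function(methyls, site, params = pre_parameters()) {
  if (nrow(methyls) == 0) stop("no methyls supplied")
  if (!inherits(site, "spin_label_site"))
    stop("'site' must come from place_electron()")
  e <- site$electron_coord
  r <- sqrt((methyls$px - e[1])^2 + (methyls$py - e[2])^2 +
            (methyls$pz - e[3])^2)
  g2 <- gamma2_H(r, params)
  data.frame(methyl_id = methyls$methyl_id, r_eN = r, gamma2_H = g2,
             gamma2_MQ = gamma2_MQ(g2, params),
             ratio = intensity_ratio(g2, params),
             stringsAsFactors = FALSE)
}

#' Compare observed and predicted PRE intensity ratios
#'
#' Joins observations and predictions on methyl id, drops unquantifiable
#' observations, and reports per-methyl residuals, the RMS residual and the
#' number of observations consistent with prediction within a tolerance.
#'
#' @param observations data.frame with \code{methyl_id}, \code{ratio} and
#'   optionally a logical \code{quantifiable} column (defaults to TRUE).
#' @param predictions output of \code{\link{predict_pre_profile}}.
#' @param tolerance ratio-units tolerance defining "consistent"
#'   (default 0.2).
#' @return An object of class \code{pre_comparison}: list with
#'   \code{per_methyl} (methyl_id, observed, predicted, residual),
#'   \code{rms}, \code{n}, \code{n_consistent}, \code{tolerance}.
#' @export
compare_pre <- function(observations, predictions, tolerance = 0.2) {
  obs <- observations
  if (is.null(obs$quantifiable)) obs$quantifiable <- TRUE
  obs <- obs[obs$quantifiable & is.finite(obs$ratio), , drop = FALSE]
  common <- intersect(obs$methyl_id, predictions$methyl_id)
  if (length(common) == 0)
    stop("no overlapping methyl ids between observations and predictions")
  o <- obs$ratio[match(common, obs$methyl_id)]
  p <- predictions$ratio[match(common, predictions$methyl_id)]
  res <- o - p
  structure(list(
    per_methyl = data.frame(methyl_id = common, observed = o, predicted = p,
                            residual = res, stringsAsFactors = FALSE),
    rms = sqrt(mean(res^2)), n = length(common),
    n_consistent = sum(abs(res) <= tolerance), tolerance = tolerance),
    class = "pre_comparison")
}

#' Localize a spin label from observed PRE ratios by grid search
#'
#' Minimizes the sum of squared differences between observed intensity
#' ratios and ratios predicted for a trial electron position, over a regular
#' 3D lattice. Deterministic: ties are broken by lexicographic grid order
#' (x fastest, then y, then z).
#'
#' @param observations data.frame with \code{methyl_id}, \code{ratio},
#'   optional \code{quantifiable}.
#' @param methyls methyl table providing pseudo-atom coordinates.
#' @param params a \code{\link{pre_parameters}} object.
#' @param step lattice spacing (\AA, default 2).
#' @param padding extension of the methyl bounding box on each side (\AA).
#' @param grid optional explicit grid as a list with numeric vectors
#'   \code{x}, \code{y}, \code{z}; overrides \code{step}/\code{padding}.
#' @return list with \code{coord} (estimated electron position),
#'   \code{objective} (sum of squared ratio residuals at the optimum),
#'   \code{n_obs}, \code{grid_dim} and a \code{collinear} warning flag for
#'   degenerate methyl geometry.
#' @export
localize_spin_label <- function(observations, methyls,
                                params = pre_parameters(),
                                step = 2, padding = 5, grid = NULL) {
  obs <- observations
  if (is.null(obs$quantifiable)) obs$quantifiable <- TRUE
  obs <- obs[obs$quantifiable & is.finite(obs$ratio), , drop = FALSE]
  keep <- match(obs$methyl_id, methyls$methyl_id)
  obs <- obs[!is.na(keep), , drop = FALSE]
  m <- methyls[stats::na.omit(keep), , drop = FALSE]
  if (nrow(obs) < 4)
    stop("need at least 4 quantifiable observations with known methyls")
  P <- cbind(m$px, m$py, m$pz)
  collinear <- FALSE
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[2] < 1e-6 * max(sv[1], 1)) {
    collinear <- TRUE
    warning("methyl coordinates are (nearly) collinear; ",
            "localization is degenerate")
  }
  if (is.null(grid)) {
    grid <- lapply(1:3, function(k) {
      rng <- range(P[, k])
      seq(rng[1] - padding, rng[2] + padding, by = step)
    })
    names(grid) <- c("x", "y", "z")
  }
  nodes <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z,
                                 KEEP.OUT.ATTRS = FALSE))
  best_sse <- Inf; best_i <- NA_integer_
  ratios <- obs$ratio
  # chunk over grid nodes to bound memory on fine grids
  chunk <- max(1L, floor(2e6 / nrow(m)))
  for (start in seq(1L, nrow(nodes), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(nodes))
    dx <- outer(nodes[idx, 1], P[, 1], "-")
    dy <- outer(nodes[idx, 2], P[, 2], "-")
    dz <- outer(nodes[idx, 3], P[, 3], "-")
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    r[r < 1e-6] <- 1e-6  # guard a node coinciding with a methyl
    pred <- intensity_ratio(gamma2_H(r, params), params)
    sse <- rowSums(sweep(pred, 2, ratios, "-")^2)
    j <- which.min(sse)   # which.min returns the first (lexicographic) min
    if (sse[j] < best_sse) {
      best_sse <- sse[j]
      best_i <- idx[j]
    }
  }
  list(coord = as.numeric(nodes[best_i, ]), objective = best_sse,
       n_obs = nrow(obs), grid_dim = lengths(grid), collinear = collinear)
}
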