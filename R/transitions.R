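#' Double-Boltzmann transition model
#'
#' Evaluates the two-step sigmoid used to describe denaturant-induced
#' transition curves of an optical parameter:
#' \deqn{y(u) = y_0 + A\left[\frac{p}{1+e^{(c_1-u)/k_1}} +
#'   \frac{1-p}{1+e^{(c_2-u)/k_2}}\right]}
#' where \eqn{c_i} are the transition midpoints (denaturant molarity at which
#' each transition is half-complete), \eqn{k_i} the transition widths in M,
#' \eqn{p} the fraction of the total amplitude \eqn{A} carried by the first
#' transition, and \eqn{y_0} the baseline. With `p = 1` the curve reduces
#' exactly to a single Boltzmann sigmoid.
#'
#' @param u Numeric vector of denaturant concentrations (M).
#' @param y0 Baseline signal.
#' @param A Total signed amplitude.
#' @param p Fraction (0-1) of the amplitude in transition 1.
#' @param c1,c2 Transition midpoints (M).
#' @param k1,k2 Transition widths (M), > 0.
#' @return Numeric vector of model values.
#' @export
double_boltzmann <- function(u, y0, A, p, c1, c2, k1, k2 = k1) {
  if (k1 <= 0 || k2 <= 0) abort("Transition widths must be > 0.")
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  y0 + A * (p / (1 + exp((c1 - u) / k1)) +
            (1 - p) / (1 + exp((c2 - u) / k2)))
}

#' Fit a denaturant transition curve with one or two Boltzmann steps
#'
#' Least-squares fit of [double_boltzmann()] to a scalar optical parameter
#' measured along a denaturant series (fluorescence lifetime, molar
#' ellipticity, intensity ratio, ...). Midpoints are initialized from the two
#' largest steps of a smoothed finite-difference derivative of the signal and
#' refined by damped least squares with box constraints
#' (widths > 0, amplitude fraction in \[0, 1\]). Estimates are returned with
#' midpoints ordered `c1 < c2`; standard errors come from the residual-scaled
#' covariance of the converged fit.
#'
#' @param curve Data frame with columns `urea_M` (>= 0, strictly increasing)
#'   and `signal`.
#' @param n_transitions 1 or 2 (default 2).
#' @param temperature Temperature in K used for derived thermodynamics
#'   (default 298.15).
#' @param init Optional named list overriding initial values
#'   (`y0`, `A`, `p`, `c1`, `c2`, `k1`, `k2`).
#' @return An object of class `transition_fit`: list with `params` (tibble of
#'   term/estimate/std_error), `thermo` (see [thermo_from_fit()]),
#'   `converged`, `warnings`, `fitted` tibble, `sigma`, `n_obs`, `temperature`.
#' @export
fit_transition <- function(curve, n_transitions = 2, temperature = 298.15,
                           init = NULL) {
  curve <- as_tibble(curve)
  if (!all(c("urea_M", "signal") %in% names(curve))) {
    abort("`curve` needs columns `urea_M` and `signal`.")
  }
  if (any(diff(curve$urea_M) <= 0)) {
    abort("`urea_M` must be strictly increasing.")
  }
  if (!n_transitions %in% 1:2) abort("`n_transitions` must be 1 or 2.")
  u <- curve$urea_M
  y <- curve$signal
  n_free <- if (n_transitions == 2) 7 else 4
  if (length(u) < 8 && n_transitions == 2) {
    warn("Fewer than 8 points for a double-transition fit.")
  }

  warnings <- character()
  if (stats::sd(y) == 0 || length(u) < n_free + 1) {
    return(new_transition_fit_failed(curve,
      "signal is constant or has too few points", n_transitions, temperature))
  }

  ini <- transition_init(u, y, n_transitions)
  if (!is.null(init)) ini[names(init)] <- init

  span <- diff(range(u))
  lower <- c(y0 = -Inf, A = -Inf, p = 0,
             c1 = min(u) - span, c2 = min(u) - span, k1 = 1e-3, k2 = 1e-3)
  upper <- c(y0 = Inf, A = Inf, p = 1,
             c1 = max(u) + span, c2 = max(u) + span, k1 = 5 * span,
             k2 = 5 * span)
  terms <- c("y0", "A", "p", "c1", "c2", "k1", "k2")
  if (n_transitions == 1) {
    terms <- c("y0", "A", "c1", "k1")
  }

  model_fun <- function(par) {
    pl <- as.list(par)
    if (n_transitions == 1) {
      double_boltzmann(u, pl$y0, pl$A, 1, pl$c1, pl$c1 + 1, pl$k1, pl$k1)
    } else {
      double_boltzmann(u, pl$y0, pl$A, pl$p, pl$c1, pl$c2, pl$k1, pl$k2)
    }
  }
  resid_fun <- function(par) y - model_fun(stats::setNames(par, terms))

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(ini[terms]), fn = resid_fun,
      lower = unname(lower[terms]), upper = unname(upper[terms]),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:3) {
    return(new_transition_fit_failed(curve,
      if (is.null(fit)) "optimizer error" else paste0("no convergence: ",
                                                      fit$message),
      n_transitions, temperature))
  }

  est <- stats::setNames(fit$par, terms)
  dof <- length(u) - length(terms)
  sigma <- sqrt(fit$deviance / max(dof, 1))
  se <- tryCatch(sqrt(pmax(diag(sigma^2 * solve(fit$hessian)), 0)),
                 error = function(e) rep(NA_real_, length(terms)))
  se <- stats::setNames(se, terms)

  if (n_transitions == 2) {
    # canonical ordering: midpoint 1 below midpoint 2
    if (est["c1"] > est["c2"]) {
      est[c("c1", "c2")] <- est[c("c2", "c1")]
      est[c("k1", "k2")] <- est[c("k2", "k1")]
      se[c("c1", "c2")] <- se[c("c2", "c1")]
      se[c("k1", "k2")] <- se[c("k2", "k1")]
      est["p"] <- 1 - est["p"]
    }
    if (est["p"] < 0.05 || est["p"] > 0.95) {
      msg <- sprintf(paste0("amplitude fraction p = %.3f: the data may ",
                            "support only a single transition"), est["p"])
      warnings <- c(warnings, msg)
      warn(msg)
    }
  } else {
    est <- c(est[c("y0", "A")], p = 1, est[c("c1", "k1")],
             c2 = NA_real_, k2 = NA_real_)
    se <- c(se[c("y0", "A")], p = NA_real_, se[c("c1", "k1")],
            c2 = NA_real_, k2 = NA_real_)
    est <- est[c("y0", "A", "p", "c1", "c2", "k1", "k2")]
    se <- se[c("y0", "A", "p", "c1", "c2", "k1", "k2")]
  }

  params <- tibble(term = names(est), estimate = unname(est),
                   std_error = unname(se))
  obj <- structure(list(
    params = params,
    n_transitions = n_transitions,
    temperature = temperature,
    converged = TRUE,
    warnings = warnings,
    sigma = sigma,
    n_obs = length(u),
    fitted = tibble(urea_M = u, signal = y,
                    fitted = model_fun(est[terms])),
    curve = curve
  ), class = "transition_fit")
  obj$thermo <- thermo_from_fit(obj, temperature = temperature)
  obj
}

transition_init <- function(u, y, n_transitions) {
  du <- diff(u)
  d <- diff(y) / du
  mid <- (u[-1] + u[-length(u)]) / 2
  if (length(d) >= 3) {
    d <- as.numeric(stats::filter(d, rep(1 / 3, 3), sides = 2))
    d[is.na(d)] <- 0
  }
  i1 <- which.max(abs(d))
  span <- diff(range(u))
  sep_ok <- abs(mid - mid[i1]) > span / 5
  i2 <- if (any(sep_ok)) which(sep_ok)[which.max(abs(d[sep_ok]))] else i1
  c1 <- min(mid[i1], mid[i2]); c2 <- max(mid[i1], mid[i2])
  s1 <- abs(d[which(mid == c1)[1]]); s2 <- abs(d[which(mid == c2)[1]])
  list(y0 = y[1], A = y[length(y)] - y[1],
       p = if (n_transitions == 2 && s1 + s2 > 0) s1 / (s1 + s2) else 1,
       c1 = c1, c2 = if (n_transitions == 2) c2 else c1 + 1,
       k1 = 0.3, k2 = 0.3)
}

new_transition_fit_failed <- function(curve, msg, n_transitions, temperature) {
  structure(list(
    params = tibble(term = c("y0", "A", "p", "c1", "c2", "k1", "k2"),
                    estimate = NA_real_, std_error = NA_real_),
    n_transitions = n_transitions, temperature = temperature,
    converged = FALSE, warnings = msg, sigma = NA_real_,
    n_obs = nrow(curve), fitted = tibble(), curve = curve,
    thermo = tibble()
  ), class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat("Denaturant transition fit (", x$n_transitions, " transition(s))\n",
      sep = "")
  if (!x$converged) {
    cat("  NOT converged:", paste(x$warnings, collapse = "; "), "\n")
    return(invisible(x))
  }
  est <- stats::setNames(x$params$estimate, x$params$term)
  cat(sprintf("  c1 = %.3f M (k1 = %.3f M)", est["c1"], est["k1"]))
  if (x$n_transitions == 2) {
    cat(sprintf(", c2 = %.3f M (k2 = %.3f M), p = %.3f", est["c2"],
                est["k2"], est["p"]))
  }
  cat(sprintf("\n  residual sd %.4g on %d points\n", x$sigma, x$n_obs))
  invisible(x)
}

#' Thermodynamic parameters from a fitted transition curve
#'
#' Maps each fitted Boltzmann step to two-state linear-extrapolation
#' thermodynamics: the m-value \eqn{m_i = RT/k_i} (kJ mol\eqn{^{-1}}
#' M\eqn{^{-1}}) and the unfolding free energy extrapolated to zero
#' denaturant, \eqn{\Delta G_{H_2O,i} = m_i c_i} (kJ mol\eqn{^{-1}}).
#' Amplitude fractions are `p` and `1 - p`. This mapping from sigmoid width
#' to m-value assumes each step is an independent two-state transition; see
#' the package vignette for the caveats.
#'
#' @param fit A converged `transition_fit`, or a named list/vector with
#'   elements `p`, `c1`, `c2`, `k1`, `k2`.
#' @param temperature Temperature in K (default 298.15).
#' @return Tibble with columns `transition`, `midpoint_M`, `width_M`,
#'   `m_kJ_per_mol_M`, `dG_H2O_kJ_per_mol`, `fraction`, `temperature_K`.
#' @export
thermo_from_fit <- function(fit, temperature = 298.15) {
  if (inherits(fit, "transition_fit")) {
    if (!fit$converged) abort("Cannot derive thermodynamics from a failed fit.")
    est <- stats::setNames(fit$params$estimate, fit$params$term)
    n_tr <- fit$n_transitions
  } else {
    est <- unlist(fit)
    if (!"p" %in% names(est)) est["p"] <- 1
    n_tr <- if (is.na(est["c2"])) 1 else 2
  }
  idx <- seq_len(n_tr)
  k <- unname(est[c("k1", "k2")][idx])
  cc <- unname(est[c("c1", "c2")][idx])
  if (any(!is.finite(k)) || any(k <= 0)) {
    abort("Transition widths must be positive to derive thermodynamics.")
  }
  m <- gas_constant_kj * temperature / k
  frac <- if (n_tr == 2) c(est["p"], 1 - est["p"]) else 1
  tibble(transition = idx, midpoint_M = cc, width_M = k,
         m_kJ_per_mol_M = m, dG_H2O_kJ_per_mol = m * cc,
         fraction = unname(frac), temperature_K = temperature)
}

#' Steady-state spectral shift ratio I320/I360
#'
#' The ratio of fluorescence intensities at 320 and 360 nm (linearly
#' interpolated), a standard scalar descriptor of tryptophan emission
#' spectral position: it grows as the spectrum blue-shifts.
#'
#' @param spectrum Data frame with columns `wavelength_nm`, `intensity`.
#' @param num_nm,den_nm Numerator/denominator wavelengths (defaults 320, 360).
#' @return A single number, or `NA` (with a warning) when the denominator
#'   intensity is zero.
#' @export
intensity_ratio <- function(spectrum, num_nm = 320, den_nm = 360) {
  spectrum <- as_tibble(spectrum)
  vals <- interp_checked(spectrum$wavelength_nm, spectrum$intensity,
                         c(num_nm, den_nm), what = "intensity")
  if (vals[2] == 0) {
    warn("Denominator intensity is zero; ratio undefined.")
    return(NA_real_)
  }
  vals[1] / vals[2]
}
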