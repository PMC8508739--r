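#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a global decay fit
#'
#' One row per estimated parameter: the shared lifetimes (with standard
#' errors) followed by the per-wavelength amplitudes and backgrounds.
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `component`, `wavelength_nm`,
#'   `estimate`, `std.error`.
#' @export
tidy.decay_fit <- function(x, ...) {
  lt <- x$lifetimes |>
    mutate(term = paste0("tau", .data$component), wavelength_nm = NA_real_) |>
    select("term", "component", "wavelength_nm",
           estimate = "lifetime_ns", std.error = "std_error_ns")
  if (!nrow(x$amplitudes)) return(lt)
  amp <- x$amplitudes |>
    mutate(term = paste0("alpha", .data$component), std.error = NA_real_) |>
    select("term", "component", "wavelength_nm",
           estimate = "amplitude", "std.error")
  bg <- x$backgrounds |>
    mutate(term = "background", component = NA_integer_,
           std.error = NA_real_) |>
    select("term", "component", "wavelength_nm",
           estimate = "background", "std.error")
  bind_rows(lt, amp, bg)
}

#' One-line summary of a global decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `chi2_global`, `chi2_reduced`, `n_obs`, `n_par`,
#'   `n_traces`, `converged`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(chi2_global = x$chi2_global, chi2_reduced = x$chi2_reduced,
         n_obs = x$n_obs, n_par = x$n_par,
         n_traces = nrow(x$backgrounds), converged = x$converged)
}

#' Tidy a transition-curve fit
#'
#' @param x A `transition_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.transition_fit <- function(x, ...) {
  x$params |> rename(std.error = "std_error")
}

#' One-line summary of a transition-curve fit
#'
#' @param x A `transition_fit`.
#' @param ... Unused.
#' @return One-row tibble: `sigma`, `n_obs`, `n_transitions`, `converged`,
#'   `temperature_K`.
#' @export
glance.transition_fit <- function(x, ...) {
  tibble(sigma = x$sigma, n_obs = x$n_obs, n_transitions = x$n_transitions,
         converged = x$converged, temperature_K = x$temperature)
}

#' Tidy a FRET pair report
#'
#' @param x A `fret_pair`.
#' @param ... Unused.
#' @return One-row tibble with the pair geometry and efficiency.
#' @export
tidy.fret_pair <- function(x, ...) {
  tibble(donor = paste0(x$donor_id$chain, ":", x$donor_id$resno),
         acceptor = paste0(x$acceptor_id$chain, ":", x$acceptor_id$resno),
         r = x$r, kappa2 = x$kappa2, efficiency = x$efficiency, r0 = x$r0,
         kappa2_min = x$kappa2_range[1] %||% NA_real_,
         kappa2_max = x$kappa2_range[2] %||% NA_real_)
}

#' Tidy a distance distribution
#'
#' @param x A `distance_distribution`.
#' @param ... Unused.
#' @return The per-frame distance tibble (`model`, `distance`).
#' @export
tidy.distance_distribution <- function(x, ...) x$distances

#' One-line summary of a distance distribution
#'
#' @param x A `distance_distribution`.
#' @param ... Unused.
#' @return One-row tibble: `n_frames`, `mean`, `sd`, `min`, `max`.
#' @export
glance.distance_distribution <- function(x, ...) x$summary
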