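#' Elastic modulus from the Theret half-space punch model
#'
#' Treating the cell as a homogeneous elastic half-space aspirated by a
#' rigid cylindrical punch, the suction pressure and normalised
#' aspiration length are related linearly,
#' `L_n = 3 Phi_p dP / (2 pi E)`, where `Phi_p` is the wall function of
#' the punch model (default 2.1 for typical wall-thickness ratios).  The
#' modulus is estimated from the least-squares slope of `dP` against
#' `L_n` over the linear (low-pressure) part of the ramp:
#' `E = 3 Phi_p slope / (2 pi)`.
#'
#' @param record an aspiration [experiment_record()] (needs columns
#'   `pressure_Pa`, `Ln`).
#' @param Phi_p punch wall function (dimensionless).
#' @param fit_fraction use pressures up to this fraction of the maximum
#'   (the linear regime; default lower half of the ramp).
#' @return object of class `modulus_fit` with `E` (Pa), the fitted
#'   slope, fit range and RMS residual.
#' @examples
#' rec <- synthetic_aspiration_record(E = 240)
#' theret_modulus(rec)$E
#' @export
theret_modulus <- function(record, Phi_p = 2.1, fit_fraction = 0.5) {
  d <- record$data
  d <- d[d$phase == "ramp" & d$Ln > 0, , drop = FALSE]
  if (nrow(d) < 3)
    stop("fit error: need >= 3 (pressure, Ln) points in the linear regime")
  d <- d[d$pressure_Pa <= fit_fraction * max(d$pressure_Pa) |
           seq_len(nrow(d)) <= 3, , drop = FALSE]
  slope <- sum(d$pressure_Pa * d$Ln) / sum(d$Ln^2) # through the origin
  if (!is.finite(slope) || slope <= 0)
    stop("fit error: nonpositive pressure-Ln slope")
  E <- 3 * Phi_p * slope / (2 * pi)
  resid <- sqrt(mean((d$pressure_Pa - slope * d$Ln)^2))
  structure(list(E = E, Phi_p = Phi_p, slope = slope,
                 fit_range = range(d$pressure_Pa), residual = resid,
                 n_points = nrow(d)),
            class = "modulus_fit")
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf("<modulus_fit> E = %.2f Pa (Phi_p = %g, %d points, RMS %.2g Pa)\n",
              x$E, x$Phi_p, x$n_points, x$residual))
  invisible(x)
}

#' Synthetic aspiration record from the half-space model
#'
#' Generates `L_n = 3 Phi_p dP / (2 pi E)` (+ optional Gaussian noise) at
#' the given pressure staircase -- the round-trip oracle for
#' [theret_modulus()].
#'
#' @param E elastic modulus (Pa).
#' @param Phi_p wall function.
#' @param pressures pressure levels (Pa).
#' @param noise_sd Gaussian noise on `Ln`.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @export
synthetic_aspiration_record <- function(E, Phi_p = 2.1,
                                        pressures = seq(10, 110, by = 10),
                                        noise_sd = 0, seed = 1L) {
  Ln <- 3 * Phi_p * pressures / (2 * pi * E)
  if (noise_sd > 0) {
    set.seed(seed)
    Ln <- pmax(Ln + stats::rnorm(length(Ln), sd = noise_sd), 0)
  }
  experiment_record(
    data.frame(time_sim = seq_along(pressures),
               time_s = seq_along(pressures),
               pressure_Pa = pressures, Lp = NA_real_, Ln = Ln,
               phase = "ramp"),
    "aspiration", meta = list(synthetic = TRUE, E = E, Phi_p = Phi_p))
}

#' Effective viscosity from constant-pressure creep
#'
#' At constant suction the aspirated length approaches a plateau,
#' `L_n(t) = L_inf (1 - exp(-t / tau))`; the creep time constant is
#' fitted by nonlinear least squares on the hold segment and converted
#' to an effective viscosity through the Kelvin-Voigt correspondence of
#' the half-space punch solution, `eta = E tau` (the longer the approach
#' to plateau at fixed stiffness, the more viscous the cell; `tau -> 0`
#' recovers the instantaneous elastic response, `eta -> 0`).
#'
#' @param record an aspiration [experiment_record()] with a hold segment
#'   (`phase == "hold"`), or any record with columns `time_s`, `Ln`.
#' @param modulus_fit a [theret_modulus()] result supplying `E`.
#' @return object of class `viscosity_fit` with `eta_mPa_s`, `tau_s`,
#'   the plateau `L_inf` and the hold pressure.
#' @export
creep_viscosity <- function(record, modulus_fit) {
  d <- record$data
  if ("phase" %in% names(d) && any(d$phase == "hold"))
    d <- d[d$phase == "hold", , drop = FALSE]
  if (nrow(d) < 4) stop("fit-window error: hold segment too short")
  t <- d$time_s - d$time_s[1]
  y <- d$Ln - d$Ln[1]
  Linf0 <- max(y)
  if (Linf0 <= 0) stop("fit-window error: no creep response in record")
  tau0 <- t[which.min(abs(y - 0.63 * Linf0))]
  if (tau0 <= 0) tau0 <- diff(range(t)) / 5
  fit <- suppressWarnings(
    stats::nls(y ~ Linf * (1 - exp(-t / tau)),
               start = list(Linf = Linf0, tau = tau0),
               control = stats::nls.control(warnOnly = TRUE)))
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  if (tau > max(t) / 2)
    stop("fit-window error: no plateau reached within the record")
  eta <- modulus_fit$E * tau # Pa s
  structure(list(eta_mPa_s = eta * 1e3, tau_s = tau,
                 L_inf = unname(cf["Linf"]),
                 hold_pressure_Pa = if ("pressure_Pa" %in% names(d))
                   d$pressure_Pa[1] else NA_real_,
                 E = modulus_fit$E),
            class = "viscosity_fit")
}

#' @export
print.viscosity_fit <- function(x, ...) {
  cat(sprintf("<viscosity_fit> eta = %.2f mPa s (tau = %.3g s, E = %.1f Pa)\n",
              x$eta_mPa_s, x$tau_s, x$E))
  invisible(x)
}

#' Synthetic creep record
#'
#' Exponential approach to plateau with known time constant -- the
#' round-trip oracle for [creep_viscosity()].
#'
#' @param L_inf plateau normalised length.
#' @param tau creep time constant (s).
#' @param times sample times (s).
#' @param pressure hold pressure (Pa).
#' @param noise_sd Gaussian noise on `Ln`.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @export
synthetic_creep_record <- function(L_inf = 0.8, tau = 1,
                                   times = seq(0, 8, by = 0.1),
                                   pressure = 117.72, noise_sd = 0,
                                   seed = 1L) {
  Ln <- L_inf * (1 - exp(-times / tau))
  if (noise_sd > 0) {
    set.seed(seed)
    Ln <- Ln + stats::rnorm(length(Ln), sd = noise_sd)
  }
  experiment_record(
    data.frame(time_sim = times, time_s = times,
               pressure_Pa = pressure, Lp = NA_real_, Ln = Ln,
               phase = "hold"),
    "aspiration", meta = list(synthetic = TRUE, tau = tau, L_inf = L_inf))
}

#' Summarise a parameter sweep
#'
#' Aggregates per-run scalar outcomes (elastic modulus or transit
#' velocity) into a tidy long-format table of mean +- SD per swept
#' parameter level.
#'
#' @param runs list of run entries, each a list with fields `parameter`
#'   (the swept value), `metric` (name, e.g. "E_Pa" or
#'   "velocity_mm_s") and `value`.
#' @param swept_parameter name of the swept parameter (recorded in the
#'   output).
#' @return data.frame(parameter, level, metric, n, mean, sd).
#' @export
sweep_summary <- function(runs, swept_parameter) {
  if (length(runs) < 1) stop("empty sweep")
  metrics <- unique(vapply(runs, `[[`, character(1), "metric"))
  kinds <- unique(vapply(runs, function(r)
    if (is.null(r$kind)) r$metric else r$kind, character(1)))
  if (length(kinds) > 1)
    stop("mixed experiment types in one sweep: ", paste(kinds, collapse = ", "))
  par <- vapply(runs, function(r) as.numeric(r$parameter), numeric(1))
  val <- vapply(runs, function(r) as.numeric(r$value), numeric(1))
  out <- do.call(rbind, lapply(sort(unique(par)), function(p) {
    v <- val[par == p]
    data.frame(parameter = swept_parameter, level = p, metric = metrics[1],
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0)
  }))
  rownames(out) <- NULL
  out
}
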