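#' Hertz contact force for a spherical indenter
#'
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`, the Hertz model
#' linking indentation depth to force for a sphere of radius `R` pressed
#' into an elastic half-space of Young's modulus `E` and Poisson ratio `nu`.
#' All quantities are SI (m, Pa, N).
#'
#' @param delta indentation depth(s) in metres (>= 0).
#' @param E Young's modulus in pascals (> 0).
#' @param R effective indenter radius in metres (> 0).
#' @param nu Poisson ratio in `[0, 0.5)`; 0.33 is the bulk-polystyrene
#'   value used for bead rigidity analysis.
#' @return Force(s) in newtons.
#' @examples
#' hertz_force(5e-9, E = 3e9, R = 1.5e-6)
#' @export
hertz_force <- function(delta, E, R, nu = 0.33) {
  if (any(delta < 0)) stop("indentation `delta` must be >= 0", call. = FALSE)
  if (E <= 0) stop("`E` must be positive", call. = FALSE)
  if (R <= 0) stop("`R` must be positive", call. = FALSE)
  if (nu < 0 || nu >= 0.5) stop("`nu` must be in [0, 0.5)", call. = FALSE)
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5
}

#' Force-indentation curve
#'
#' Stores samples in SI units; the constructor takes the instrument-side
#' nm / nN convention and converts (noted once per session via a message).
#'
#' @param delta_nm indentation samples in nanometres.
#' @param force_nN force samples in nanonewtons.
#' @param R_nm probe (bead) radius in nanometres.
#' @param nu Poisson ratio.
#' @return An object of class `force_curve` with fields `delta` (m),
#'   `force` (N), `R` (m), `nu`.
#' @export
force_curve <- function(delta_nm, force_nN, R_nm, nu = 0.33) {
  if (length(delta_nm) != length(force_nN))
    stop("delta and force must have equal length", call. = FALSE)
  if (!all(is.finite(delta_nm)) || !all(is.finite(force_nN)))
    stop("curve samples must be finite", call. = FALSE)
  if (R_nm <= 0) stop("probe radius must be positive", call. = FALSE)
  message_once("force_curve: converting nm/nN input to SI (m, N)")
  structure(list(delta = delta_nm * 1e-9, force = force_nN * 1e-9,
                 R = R_nm * 1e-9, nu = nu),
            class = "force_curve")
}

.io_msg_env <- new.env(parent = emptyenv())
message_once <- function(msg) {
  if (!isTRUE(.io_msg_env[[msg]])) {
    message(msg)
    .io_msg_env[[msg]] <- TRUE
  }
  invisible(NULL)
}

#' Fit the Hertz model to a force-indentation curve
#'
#' Least-squares fit of Young's modulus `E` and the contact-point offset
#' `delta0` to `F = (4/3) (E / (1 - nu^2)) sqrt(R) max(delta - delta0, 0)^
#' (3/2)`, with `R` and `nu` known. `delta0` can be pinned instead of
#' fitted. Uses Levenberg-Marquardt least squares.
#'
#' @param curve a [force_curve()].
#' @param fix_delta0 optional fixed contact-point offset in metres; when
#'   `NULL` (default) `delta0` is fitted jointly with `E`.
#' @return An object of class `hertz_params`: `E` (Pa), `nu`, `R` (m),
#'   `delta0` (m), `rms` residual (N), `n` samples used.
#' @export
fit_hertz <- function(curve, fix_delta0 = NULL) {
  if (!inherits(curve, "force_curve"))
    stop("`curve` must be a force_curve", call. = FALSE)
  delta <- curve$delta; force <- curve$force
  if (sum(delta > 0) < 10L)
    stop("need at least 10 post-contact samples", call. = FALSE)
  # fit in nm / nN / GPa so both parameters are O(1) and the Jacobian is
  # well conditioned
  x <- delta * 1e9; y <- force * 1e9
  k_geom <- (4 / 3) * sqrt(curve$R) / (1 - curve$nu^2)
  k_nm <- k_geom * sqrt(1e-9) * 1e9     # nN = k_nm * E_gpa * nm^(3/2)
  pos <- x > 0 & y > 0
  E0 <- stats::median(y[pos] / (k_nm * x[pos]^1.5))
  fit <- tryCatch({
    if (is.null(fix_delta0)) {
      minpack.lm::nlsLM(
        y ~ k_nm * E_gpa * pmax(x - d0_nm, 0)^1.5,
        start = list(E_gpa = E0, d0_nm = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      d0_nm <- fix_delta0 * 1e9
      minpack.lm::nlsLM(
        y ~ k_nm * E_gpa * pmax(x - d0_nm, 0)^1.5,
        start = list(E_gpa = E0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e)
    stop("Hertz fit did not converge: ", conditionMessage(e),
         call. = FALSE))
  cf <- stats::coef(fit)
  E_hat <- unname(cf[["E_gpa"]]) * 1e9
  d0_hat <- if (is.null(fix_delta0)) unname(cf[["d0_nm"]]) * 1e-9 else
    fix_delta0
  if (E_hat <= 0)
    stop("fitted Young's modulus is not positive (E = ", signif(E_hat, 3),
         " Pa)", call. = FALSE)
  structure(list(E = E_hat, nu = curve$nu, R = curve$R, delta0 = d0_hat,
                 rms = sqrt(mean(stats::resid(fit)^2)) * 1e-9,
                 n = length(delta)),
            class = "hertz_params")
}

#' @export
print.hertz_params <- function(x, ...) {
  cat(sprintf(
    "<hertz_params> E = %.4g Pa, nu = %.2f, R = %.3g m, delta0 = %.3g m\n",
    x$E, x$nu, x$R, x$delta0))
  invisible(x)
}

#' Internalized volume and surface area of spherical beads
#'
#' Per-cell totals `count * (4/3) pi r^3` and `count * 4 pi r^2` with
#' `r = diameter / 2`, the geometry bookkeeping behind bead-uptake capacity
#' comparisons.
#'
#' @param diameter_um bead diameter in micrometres (> 0).
#' @param count beads internalized (>= 0; vectorized).
#' @return List with `volume_um3` and `surface_um2`.
#' @export
internalized_geometry <- function(diameter_um, count) {
  if (any(diameter_um <= 0))
    stop("bead diameter must be positive", call. = FALSE)
  if (any(count < 0)) stop("bead count must be >= 0", call. = FALSE)
  r <- diameter_um / 2
  list(volume_um3 = count * (4 / 3) * pi * r^3,
       surface_um2 = count * 4 * pi * r^2)
}

#' Phagocytosis-efficiency summaries from per-cell bead counts
#'
#' The labeling protocol distinguishes internalized beads (protected from
#' the surface stain) from uninternalized ones, yielding per-cell counts.
#' Because "efficiency" can be defined per cell or per bead, both standard
#' summaries are reported: the fraction of cells with at least one
#' internalized bead and the mean number of internalized beads per cell,
#' along with the count distribution.
#'
#' @param internalized integer vector, internalized beads per cell.
#' @param surface_bound optional integer vector, surface-bound beads per
#'   cell (same length), summarized when given.
#' @return List: `n_cells`, `fraction_engulfing`, `mean_internalized`,
#'   `distribution` (table of counts), and `mean_surface_bound` if provided.
#' @export
phagocytosis_efficiency <- function(internalized, surface_bound = NULL) {
  if (length(internalized) == 0L)
    stop("empty cell list", call. = FALSE)
  if (any(internalized < 0))
    stop("counts must be >= 0", call. = FALSE)
  out <- list(n_cells = length(internalized),
              fraction_engulfing = mean(internalized >= 1),
              mean_internalized = mean(internalized),
              distribution = table(internalized))
  if (!is.null(surface_bound)) {
    if (length(surface_bound) != length(internalized) ||
        any(surface_bound < 0))
      stop("`surface_bound` must match `internalized` and be >= 0",
           call. = FALSE)
    out$mean_surface_bound <- mean(surface_bound)
  }
  out
}
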