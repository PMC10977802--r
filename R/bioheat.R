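# Pennes bioheat solver and CEM43 thermal dose accumulation.
#
# Explicit forward-time centred-space (FTCS) discretization of
#   rho c_p dT/dt = div(k grad T) + Q - w_b c_b (T - T_a)
# on a regular voxel grid, Dirichlet T = T_a on the domain faces.

# shift a 3-D array by one voxel along `axis` in direction `dir`,
# filling the vacated face with `fill`
shift_arr <- function(a, axis, dir, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (dir > 0) { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1) }
  else         { src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighbour sum with Dirichlet fill
neighbour_sum <- function(T, fill) {
  shift_arr(T, 1, +1, fill) + shift_arr(T, 1, -1, fill) +
    shift_arr(T, 2, +1, fill) + shift_arr(T, 2, -1, fill) +
    shift_arr(T, 3, +1, fill) + shift_arr(T, 3, -1, fill)
}

# largest stable explicit time step, s
pennes_dt_max <- function(tissue, h_mm) {
  h <- h_mm / 1000
  tissue$rho * tissue$c_p / (6 * tissue$k / h^2 + max(tissue$w_b) * tissue$c_b)
}

# one FTCS step; T, Q arrays (Q in W/m3), returns updated T with
# boundary faces clamped to T_a
pennes_step <- function(T, Q, tissue, dt, h_mm) {
  h <- h_mm / 1000
  Ta <- tissue$T_a
  lap <- (neighbour_sum(T, Ta) - 6 * T) / h^2
  T2 <- T + dt / (tissue$rho * tissue$c_p) *
    (tissue$k * lap + Q - tissue$w_b * tissue$c_b * (T - Ta))
  d <- dim(T2)
  T2[c(1, d[1]), , ] <- Ta; T2[, c(1, d[2]), ] <- Ta; T2[, , c(1, d[3])] <- Ta
  T2
}

#' Volumetric heating rate from an acoustic intensity field
#'
#' Absorption heating \eqn{Q = 2 \alpha_{abs} I}, with the absorbed
#' attenuation converted from dB/cm to Np/m and the intensity from W/cm2 to
#' W/m2.
#'
#' @param intensity an `intensity_field` (W/cm2) or a bare numeric array of
#'   intensities in W/cm2.
#' @param medium an `acoustic_medium` (attenuation may be a voxel array via
#'   `alpha`), or a `tissue_phantom`.
#' @param f_mhz frequency at which to evaluate the attenuation power law,
#'   MHz (default 1).
#' @return numeric array `Q`, W/m3, on the grid of `intensity`.
#' @export
heat_source_from_intensity <- function(intensity, medium, f_mhz = 1) {
  I <- if (inherits(intensity, "intensity_field")) intensity$I else intensity
  if (inherits(medium, "tissue_phantom")) medium <- medium$acoustic
  a_np_m <- absorption_np_m(medium, f_mhz)
  if (length(a_np_m) > 1 && !identical(dim(a_np_m), dim(I)))
    stop("grid mismatch between intensity and medium absorption")
  2 * a_np_m * I * 1e4                       # W/cm2 -> W/m2
}

#' Solve the Pennes bioheat equation
#'
#' Explicit FTCS integration with Dirichlet boundary (faces held at
#' `tissue$T_a`). The stability bound
#' \eqn{\Delta t \le \rho c_p / (6k/h^2 + w_b c_b)} is enforced; an
#' unstable request is refused with a suggested step.
#'
#' @param T0 initial temperature: scalar (uniform) or array, degrees C.
#' @param Q volumetric heat source array, W/m3 (scalar 0 allowed).
#' @param tissue a `thermal_tissue`.
#' @param h_mm voxel edge length, mm.
#' @param dt time step, s.
#' @param duration total integration time, s.
#' @param stride snapshot stride (every `stride`-th step is recorded).
#' @param dim3 grid dimensions, required when both `T0` and `Q` are scalars.
#' @return a `temperature_history`: list with `snapshots` (list of arrays),
#'   `times` (s), `dt_snapshot` (s) and `final` (last temperature array).
#' @examples
#' tis <- thermal_tissue(w_b = 0)
#' h <- pennes_solve(37, 0, tis, h_mm = 1, dt = 0.05, duration = 1,
#'                   dim3 = c(9, 9, 9))
#' max(abs(h$final - 37))
#' @export
pennes_solve <- function(T0, Q, tissue, h_mm, dt, duration, stride = 1L,
                         dim3 = NULL) {
  dims <- if (!is.null(dim(T0))) dim(T0)
  else if (!is.null(dim(Q))) dim(Q)
  else dim3
  if (is.null(dims)) stop("grid dimensions could not be inferred; give dim3")
  if (is.null(dim(T0))) T0 <- array(T0, dims)
  if (is.null(dim(Q))) Q <- array(Q, dims)
  if (!identical(dim(T0), dim(Q))) stop("T0 and Q grids do not match")
  if (any(Q < 0)) stop("heat source Q must be non-negative")
  dtmax <- pennes_dt_max(tissue, h_mm)
  if (dt > dtmax)
    stop(sprintf("unstable time step: dt = %.4g s exceeds the explicit bound %.4g s; use dt <= %.4g",
                 dt, dtmax, 0.9 * dtmax))
  nt <- round(duration / dt)
  if (abs(nt * dt - duration) > 1e-9 * max(1, duration))
    stop("duration must be an integer multiple of dt")
  T <- T0
  keep <- seq_len(nt)[seq_len(nt) %% stride == 0L]
  snapshots <- vector("list", length(keep))
  j <- 0L
  for (i in seq_len(nt)) {
    T <- pennes_step(T, Q, tissue, dt, h_mm)
    if (i %% stride == 0L) { j <- j + 1L; snapshots[[j]] <- T }
  }
  structure(list(snapshots = snapshots, times = keep * dt,
                 dt_snapshot = dt * stride, final = T),
            class = "temperature_history")
}

# CEM43 accumulation rate in equivalent-minutes per minute; the exponent is
# clamped at 100 degrees above 43 so that dose stays finite when the linear
# model drives focal temperatures to unphysical values
cem43_rate <- function(T, clamp = 100) {
  R <- ifelse(T >= 43, 0.5, 0.25)
  R^(pmax(43 - T, -clamp))
}

#' Accumulate CEM43 thermal dose over a temperature history
#'
#' Sapareto-Dean cumulative equivalent minutes at 43 degrees C:
#' \eqn{CEM43 = \sum_t R^{43 - T_t} \Delta t} with R = 0.5 for
#' T >= 43 and 0.25 below. Dose is additive over concatenated histories.
#'
#' @param history a `temperature_history`, or a list of temperature arrays.
#' @param dose an existing `dose_field` to add to, or `NULL` to start at 0.
#' @param dt_min snapshot spacing in minutes; taken from the history when
#'   available, required (uniform) otherwise.
#' @param threshold ablation threshold stored on the dose field, equivalent
#'   minutes (default 240).
#' @return a `dose_field`: list with array `cem43` (min) and `threshold`.
#' @examples
#' hist <- list(array(44, c(2, 2, 2)))
#' cem43_accumulate(hist, dt_min = 1)$cem43[1]  # one minute at 44 C = 2 min
#' @export
cem43_accumulate <- function(history, dose = NULL, dt_min = NULL,
                             threshold = 240) {
  if (inherits(history, "temperature_history")) {
    if (is.null(dt_min)) dt_min <- history$dt_snapshot / 60
    snaps <- history$snapshots
  } else snaps <- history
  if (is.null(dt_min))
    stop("snapshot spacing is not uniform or not supplied; give dt_min")
  acc <- if (is.null(dose)) 0 else dose$cem43
  for (T in snaps) acc <- acc + cem43_rate(T) * dt_min
  if (is.null(dose))
    structure(list(cem43 = acc, threshold = threshold), class = "dose_field")
  else { dose$cem43 <- acc; dose }
}

#' Ablated volume from a thermal dose field
#'
#' Counts voxels at or above the CEM43 ablation threshold (inclusive) and
#' converts to cm3. This is the simulated analogue of the nonperfused volume
#' measured on contrast MRI.
#'
#' @param dose a `dose_field`.
#' @param voxel_volume voxel volume, mm3.
#' @param threshold equivalent minutes at 43 C; defaults to the dose field's
#'   stored threshold (240 min).
#' @return ablated volume, cm3.
#' @export
ablated_volume <- function(dose, voxel_volume, threshold = dose$threshold) {
  if (threshold <= 0) stop("ablation threshold must be positive")
  sum(dose$cem43 >= threshold) * voxel_volume / 1000
}
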