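# Sonication parameter sets, multi-point treatment planning, and full
# treatment simulation (pulsed heating per point, cooling during
# transitions).

#' Sonication parameter set
#'
#' The seven protocol knobs of a multi-point HIFU treatment.
#'
#' @param point_interval spacing of the treatment-point lattice, mm.
#' @param focal_intensity spatial-peak focal intensity in situ, kW/cm2.
#' @param duty_cycle emission duty cycle, percent in (0, 100].
#' @param center_frequency drive frequency, MHz.
#' @param prf pulse repetition frequency, Hz.
#' @param per_point_time treatment time per point, s.
#' @param transition_time inter-point transition (cooling) time, s.
#' @param label free-text label.
#' @return an object of class `sonication_params`.
#' @seealso [sonication_preset()] for the Group A/B presets.
#' @export
sonication_params <- function(point_interval, focal_intensity, duty_cycle,
                              center_frequency, prf, per_point_time,
                              transition_time, label = "custom") {
  v <- c(point_interval, focal_intensity, duty_cycle, center_frequency,
         prf, per_point_time, transition_time)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all sonication parameters must be positive")
  if (duty_cycle > 100) stop("duty_cycle must lie in (0, 100]")
  structure(list(point_interval = point_interval,
                 focal_intensity = focal_intensity,
                 duty_cycle = duty_cycle,
                 center_frequency = center_frequency,
                 prf = prf,
                 per_point_time = per_point_time,
                 transition_time = transition_time,
                 label = label),
            class = "sonication_params")
}

#' Treatment-protocol presets
#'
#' Group A is the conventional uterine-fibroid parameter set; Group B is the
#' simulation-optimized adenomyosis set (denser lattice, higher intensity and
#' duty cycle, longer per-point time).
#'
#' @param group `"A"` or `"B"`.
#' @return a `sonication_params`.
#' @examples
#' sonication_preset("B")
#' @export
sonication_preset <- function(group) {
  switch(as.character(group),
    A = sonication_params(4, 0.8, 60, 1.0, 10, 6, 3, label = "A"),
    B = sonication_params(2, 1.0, 70, 1.0, 10, 7, 3, label = "B"),
    stop("unknown preset '", group, "'; valid presets are \"A\" and \"B\""))
}

#' @export
print.sonication_params <- function(x, ...) {
  cat(sprintf(paste0("Sonication parameters [%s]: interval %g mm, ",
                     "intensity %g kW/cm2, duty %g%%, f0 %g MHz, PRF %g Hz,\n",
                     "  per-point time %g s, transition %g s\n"),
              x$label, x$point_interval, x$focal_intensity, x$duty_cycle,
              x$center_frequency, x$prf, x$per_point_time,
              x$transition_time))
  invisible(x)
}

#' Ellipsoidal lesion descriptor
#' @param semiaxes semi-axis lengths `c(ax, ay, az)`, mm.
#' @param center lesion centre, mm (default origin).
#' @return a `lesion_ellipsoid`.
#' @export
lesion_ellipsoid <- function(semiaxes, center = c(0, 0, 0)) {
  if (any(semiaxes <= 0)) stop("lesion semi-axes must be positive")
  structure(list(center = center, semiaxes = semiaxes),
            class = "lesion_ellipsoid")
}

#' Plan a multi-point sonication lattice for an ellipsoidal lesion
#'
#' Lays a cubic lattice of spacing `params$point_interval` over the lesion,
#' keeps points strictly inside the ellipsoid, and excludes a deep-margin
#' slab: no point lies deeper than the deepest lesion extent minus
#' `deep_margin` (the protocol targets no closer than one centimetre above
#' the deepest lesion margin; larger z = deeper, away from the transducer).
#' Points are ordered shallow-to-deep by plane, boustrophedon within each
#' plane (rows by y, alternating x direction).
#'
#' @param lesion a `lesion_ellipsoid`, or a `tissue_phantom` (its lesion is
#'   used).
#' @param params a `sonication_params`.
#' @param deep_margin deep-margin offset, mm (default 10).
#' @return a `treatment_plan`: data.frame with columns `order`, `x`, `y`,
#'   `z` (mm) and attributes `lesion`, `spacing`, `deep_margin`.
#' @examples
#' plan_grid(lesion_ellipsoid(c(15, 15, 15)), sonication_preset("A"))
#' @export
plan_grid <- function(lesion, params, deep_margin = 10) {
  if (inherits(lesion, "tissue_phantom"))
    lesion <- lesion_ellipsoid(lesion$lesion_semiaxes)
  stopifnot(inherits(lesion, "lesion_ellipsoid"))
  s <- params$point_interval
  ctr <- lesion$center; ax <- lesion$semiaxes
  z_deep_limit <- ctr[3] + ax[3] - deep_margin
  offs <- function(a) s * seq(-ceiling(a / s), ceiling(a / s))
  g <- expand.grid(x = ctr[1] + offs(ax[1]),
                   y = ctr[2] + offs(ax[2]),
                   z = ctr[3] + offs(ax[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  g <- g[inside & g$z <= z_deep_limit + 1e-9, , drop = FALSE]
  if (nrow(g) == 0)
    stop("empty plan: no lattice point lies inside the lesion above the deep margin")
  # shallow-to-deep planes; boustrophedon rows within each plane
  g <- g[order(g$z, g$y, g$x), , drop = FALSE]
  parts <- split(g, list(factor(g$z), factor(g$y)), drop = TRUE)
  key <- vapply(parts, function(p) c(p$z[1], p$y[1]), numeric(2))
  parts <- parts[order(key[1, ], key[2, ])]
  zprev <- NULL; row_i <- 0L
  parts <- lapply(parts, function(p) p)  # materialize
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (is.null(zprev) || p$z[1] != zprev) { row_i <- 0L; zprev <- p$z[1] }
    if (row_i %% 2L == 1L) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    row_i <- row_i + 1L
    out[[i]] <- p
  }
  g <- do.call(rbind, out)
  plan <- data.frame(order = seq_len(nrow(g)), x = g$x, y = g$y, z = g$z)
  rownames(plan) <- NULL
  structure(plan, lesion = lesion, spacing = s, deep_margin = deep_margin,
            class = c("treatment_plan", "data.frame"))
}

#' Protocol timing for an n-point treatment
#'
#' Total protocol duration is `n * per_point_time + (n - 1) * transition_time`
#' and the emitted on-time ("sonication time") is
#' `n * per_point_time * duty_cycle / 100`.
#'
#' @param n_points number of treatment points.
#' @param params a `sonication_params`.
#' @return list with `duration_s` and `on_time_s`.
#' @examples
#' treatment_timing(10, sonication_preset("B"))  # 97 s, 49 s
#' @export
treatment_timing <- function(n_points, params) {
  list(duration_s = n_points * params$per_point_time +
         (n_points - 1) * params$transition_time,
       on_time_s = n_points * params$per_point_time * params$duty_cycle / 100)
}

#' Normalized focal intensity template for a bowl in a homogeneous medium
#'
#' Computes the hybrid (Rayleigh + angular spectrum) field of the bowl on a
#' grid around the focus and returns the intensity normalized to unit peak,
#' together with the voxel offsets of each template sample relative to the
#' peak. The template is translated to each treatment point during a
#' simulated treatment (homogeneous focal-neighbourhood assumption), and by
#' linearity it can be rescaled to any calibrated focal intensity.
#'
#' @param geometry a `hifu_array`; default is the package's representative
#'   abdominal bowl (F = 130 mm, a = 64 mm) at `f_mhz`.
#' @param medium homogeneous `acoustic_medium`; default myometrium-like.
#' @param spacing grid spacing, mm (should equal the thermal voxel size).
#' @param lateral_halfwidth,axial_halfwidth template half-extents, mm.
#' @param f_mhz drive frequency for the default geometry, MHz.
#' @return an `intensity_template`: list with array `I` (peak 1), integer
#'   offset vectors `ox`, `oy`, `oz` (voxels relative to the peak), and
#'   `spacing`.
#' @export
focal_intensity_template <- function(geometry = NULL,
                                     medium = acoustic_medium(
                                       c = 1540, rho = 1050, alpha = 0.5),
                                     spacing = 0.5,
                                     lateral_halfwidth = 10,
                                     axial_halfwidth = 15,
                                     f_mhz = 1.0) {
  if (is.null(geometry)) geometry <- discretize_bowl(130, 64, f_mhz)
  F <- geometry$focal_length
  fld <- simulate_field(geometry, medium,
                        z_range = F + c(-axial_halfwidth, axial_halfwidth),
                        lateral_halfwidth = lateral_halfwidth,
                        spacing = spacing)
  I <- intensity_field(fld, medium)$I
  pk <- which(I == max(I), arr.ind = TRUE)[1, ]
  structure(list(I = I / max(I),
                 ox = seq_len(dim(I)[1]) - pk[1],
                 oy = seq_len(dim(I)[2]) - pk[2],
                 oz = seq_len(dim(I)[3]) - pk[3],
                 spacing = spacing),
            class = "intensity_template")
}

# place `template$I * scale` into an array of dims `dims` with the template
# peak at voxel index `at` (length-3 integer); clips at the boundary
embed_template <- function(template, dims, at, scale = 1) {
  Q <- array(0, dims)
  ix <- at[1] + template$ox; iy <- at[2] + template$oy; iz <- at[3] + template$oz
  kx <- which(ix >= 1 & ix <= dims[1])
  ky <- which(iy >= 1 & iy <= dims[2])
  kz <- which(iz >= 1 & iz <= dims[3])
  Q[ix[kx], iy[ky], iz[kz]] <- template$I[kx, ky, kz] * scale
  Q
}

# pick a time step that divides `segment` seconds and respects dtmax
fit_dt <- function(segment, dtmax, dt0 = 0.1) {
  n <- ceiling(segment / min(dt0, 0.9 * dtmax))
  segment / n
}

#' Simulate a full multi-point HIFU treatment
#'
#' Replays the protocol point by point: for each planned point the focal
#' intensity template is translated to the point and the Pennes equation is
#' integrated for `per_point_time` with the heat source on, then for
#' `transition_time` with the source off (no transition after the last
#' point), accumulating CEM43 dose throughout. The default duty-cycle model
#' is time-averaged heating (`Q * duty/100`); explicit on/off pulsing at the
#' PRF is available with `pulsing = "explicit"`.
#'
#' @param plan a `treatment_plan`.
#' @param params a `sonication_params`.
#' @param phantom a `tissue_phantom`.
#' @param geometry optional `hifu_array` for the template beam.
#' @param template optional precomputed `intensity_template` (its spacing
#'   must equal the phantom voxel size); computed if `NULL`.
#' @param dt optional time step, s; chosen automatically if `NULL`. In
#'   explicit mode a supplied `dt` must divide both the on and off segments
#'   of the pulse period or the run is refused.
#' @param pulsing `"averaged"` (default) or `"explicit"`.
#' @param dose_threshold CEM43 ablation threshold, min.
#' @return a `treatment_result`: list with `dose` (a `dose_field`),
#'   `per_point_peak_T` (degrees C), `ablated_cm3`, `duration_s`,
#'   `on_time_s`, `plan`, `params`.
#' @export
simulate_treatment <- function(plan, params, phantom, geometry = NULL,
                               template = NULL, dt = NULL,
                               pulsing = c("averaged", "explicit"),
                               dose_threshold = 240) {
  pulsing <- match.arg(pulsing)
  if (is.null(template))
    template <- focal_intensity_template(geometry, medium = phantom$acoustic,
                                         spacing = phantom$voxel,
                                         f_mhz = params$center_frequency)
  if (abs(template$spacing - phantom$voxel) > 1e-9)
    stop("template spacing does not match the phantom voxel size")
  dims <- dim(phantom$lesion_mask)
  tissue <- phantom$thermal
  h <- phantom$voxel
  dtmax <- pennes_dt_max(tissue, h)
  I_wcm2 <- params$focal_intensity * 1000            # kW/cm2 -> W/cm2
  q_scale <- 2 * absorption_np_m(phantom$acoustic, params$center_frequency) *
    I_wcm2 * 1e4                                     # peak Q, W/m3
  tp <- params$per_point_time; tt <- params$transition_time
  duty <- params$duty_cycle / 100

  if (pulsing == "explicit") {
    period <- 1 / params$prf
    seg_on <- duty * period; seg_off <- period - seg_on
    if (is.null(dt)) {
      g <- gcd_int(round(params$duty_cycle), 100 - round(params$duty_cycle))
      dt <- period * g / 100
    }
    bad <- function(seg) seg > 1e-12 &&
      abs(seg / dt - round(seg / dt)) > 1e-9
    if (bad(seg_on) || bad(seg_off) || dt > dtmax)
      stop("dt incompatible with PRF pulsing: the step must divide both the ",
           "on and off segments of the pulse period and satisfy the ",
           sprintf("stability bound %.4g s", dtmax))
    n_periods <- round(tp / period)
    if (abs(n_periods * period - tp) > 1e-9)
      stop("per_point_time must be an integer number of pulse periods in ",
           "explicit mode")
  } else {
    dt <- if (is.null(dt)) fit_dt(tp, dtmax) else dt
    if (dt > dtmax)
      stop(sprintf("unstable dt; use dt <= %.4g s", 0.9 * dtmax))
  }
  dt_off <- fit_dt(tt, dtmax, dt0 = dt)

  # map plan points to voxel indices
  to_idx <- function(p, coords) round((p - coords[1]) / h) + 1L
  T <- array(tissue$T_a, dims)
  dose_acc <- array(0, dims)
  n <- nrow(plan)
  peaks <- numeric(n)
  run_phase <- function(T, Q, dt, nsteps) {
    pk <- -Inf; dmin <- dt / 60
    for (s in seq_len(nsteps)) {
      T <- pennes_step(T, Q, tissue, dt, h)
      dose_acc <<- dose_acc + cem43_rate(T) * dmin
      pk <- max(pk, max(T))
    }
    list(T = T, peak = pk)
  }
  Q0 <- array(0, dims)
  for (i in seq_len(n)) {
    at <- c(to_idx(plan$x[i], phantom$x), to_idx(plan$y[i], phantom$y),
            to_idx(plan$z[i], phantom$z))
    Qp <- embed_template(template, dims, at, scale = q_scale)
    if (pulsing == "averaged") {
      ph <- run_phase(T, Qp * duty, dt, round(tp / dt))
      T <- ph$T; peaks[i] <- ph$peak
    } else {
      n_on <- round(seg_on / dt); n_off <- round(seg_off / dt)
      pk <- -Inf
      for (cyc in seq_len(n_periods)) {
        ph <- run_phase(T, Qp, dt, n_on); T <- ph$T; pk <- max(pk, ph$peak)
        if (n_off > 0) {
          ph <- run_phase(T, Q0, dt, n_off); T <- ph$T; pk <- max(pk, ph$peak)
        }
      }
      peaks[i] <- pk
    }
    if (i < n) {
      ph <- run_phase(T, Q0, dt_off, round(tt / dt_off))
      T <- ph$T; peaks[i] <- max(peaks[i], ph$peak)
    }
  }
  dose <- structure(list(cem43 = dose_acc, threshold = dose_threshold),
                    class = "dose_field")
  timing <- treatment_timing(n, params)
  structure(list(dose = dose,
                 per_point_peak_T = peaks,
                 peak_T = max(peaks),
                 peak_cem43 = max(dose_acc),
                 ablated_cm3 = ablated_volume(dose, h^3),
                 duration_s = timing$duration_s,
                 on_time_s = timing$on_time_s,
                 final_T = T, plan = plan, params = params),
            class = "treatment_result")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' @export
print.treatment_result <- function(x, ...) {
  cat(sprintf(paste0("Treatment result [%s]: %d points\n",
                     "  duration %.0f s (on-time %.0f s), peak T %.1f C, ",
                     "peak CEM43 %.3g min\n  ablated volume %.3f cm3 ",
                     "(threshold %g min)\n"),
              x$params$label, nrow(x$plan), x$duration_s, x$on_time_s,
              x$peak_T, x$peak_cem43, x$ablated_cm3, x$dose$threshold))
  invisible(x)
}

#' @export
summary.treatment_result <- function(object, ...) {
  data.frame(label = object$params$label,
             n_points = nrow(object$plan),
             duration_s = object$duration_s,
             on_time_s = object$on_time_s,
             peak_T_C = object$peak_T,
             peak_cem43_min = object$peak_cem43,
             ablated_cm3 = object$ablated_cm3)
}
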