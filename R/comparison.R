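# Parameter-set comparison across tissue scenarios, and perfusion
# sensitivity sweeps. These reproduce the optimization rationale behind the
# adenomyosis-specific parameter set: because adenomyotic tissue is better
# perfused than fibroid tissue, the same protocol deposits less thermal dose
# in it, and a denser/hotter/longer protocol compensates.

# single-point plan at the lesion centre
single_point_plan <- function(params) {
  structure(data.frame(order = 1L, x = 0, y = 0, z = 0),
            lesion = lesion_ellipsoid(c(1, 1, 1)), spacing =
              params$point_interval, deep_margin = 0,
            class = c("treatment_plan", "data.frame"))
}

# 3 x 3 x 1 mini-grid plan at the lattice spacing of `params`
mini_grid_plan <- function(params) {
  s <- params$point_interval
  g <- expand.grid(x = s * (-1:1), y = s * (-1:1), z = 0)
  structure(data.frame(order = seq_len(nrow(g)), x = g$x, y = g$y, z = g$z),
            lesion = lesion_ellipsoid(rep(2 * s, 3)), spacing = s,
            deep_margin = 0,
            class = c("treatment_plan", "data.frame"))
}

#' Compare sonication parameter sets across tissue scenarios
#'
#' Runs one deterministic [simulate_treatment()] per (parameter set,
#' phantom) pair on a standardized plan — a single focal point by default,
#' isolating per-point physics, or a 3 x 3 mini-grid (`plan_type = "grid"`)
#' which also exposes the point-interval effect — and tabulates peak
#' temperature, peak CEM43 dose, ablated volume and ablation rate.
#'
#' @param param_sets list of `sonication_params`.
#' @param phantoms list of `tissue_phantom` (all on identical grids).
#' @param plan_type `"single"` or `"grid"`.
#' @param geometry optional `hifu_array` for the template beam.
#' @param template optional precomputed `intensity_template`.
#' @return a `comparison_report` data.frame with one row per
#'   (label, scenario): `peak_T_C`, `peak_cem43_min`, `ablated_cm3`,
#'   `cm3_per_min`.
#' @export
compare_params <- function(param_sets, phantoms,
                           plan_type = c("single", "grid"),
                           geometry = NULL, template = NULL) {
  plan_type <- match.arg(plan_type)
  if (inherits(param_sets, "sonication_params")) param_sets <- list(param_sets)
  if (inherits(phantoms, "tissue_phantom")) phantoms <- list(phantoms)
  if (length(param_sets) < 1 || length(phantoms) < 1)
    stop("need at least one parameter set and one phantom")
  dims <- lapply(phantoms, function(p) dim(p$lesion_mask))
  vox <- vapply(phantoms, function(p) p$voxel, numeric(1))
  if (length(unique(vox)) > 1 ||
      any(!vapply(dims, identical, logical(1), dims[[1]])))
    stop("inconsistent grids across scenarios")
  if (is.null(template))
    template <- focal_intensity_template(geometry,
                                         medium = phantoms[[1]]$acoustic,
                                         spacing = vox[1])
  rows <- list()
  for (ph in phantoms) for (ps in param_sets) {
    plan <- if (plan_type == "single") single_point_plan(ps)
    else mini_grid_plan(ps)
    res <- simulate_treatment(plan, ps, ph, template = template)
    rows[[length(rows) + 1L]] <- data.frame(
      label = ps$label, scenario = ph$scenario,
      peak_T_C = res$peak_T, peak_cem43_min = res$peak_cem43,
      ablated_cm3 = res$ablated_cm3,
      cm3_per_min = res$ablated_cm3 / (res$duration_s / 60))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Ablated volume as a function of tissue perfusion
#'
#' Runs one deterministic single-point treatment per perfusion value, with
#' the phantom's perfusion rate set uniformly to each value. Because
#' perfusion only removes heat, the resulting ablated-volume curve is
#' monotone non-increasing.
#'
#' @param params a `sonication_params`.
#' @param w_b_values sorted non-negative perfusion rates, kg/(m3 s).
#' @param phantom a `tissue_phantom` providing grid and acoustic background.
#' @param geometry,template as in [compare_params()].
#' @return data.frame with `w_b`, `peak_T_C`, `peak_cem43_min`,
#'   `ablated_cm3`.
#' @export
perfusion_sweep <- function(params, w_b_values, phantom = generate_phantom(),
                            geometry = NULL, template = NULL) {
  if (any(w_b_values < 0)) stop("perfusion rates must be non-negative")
  if (is.unsorted(w_b_values)) stop("w_b_values must be sorted increasing")
  if (is.null(template))
    template <- focal_intensity_template(geometry, medium = phantom$acoustic,
                                         spacing = phantom$voxel)
  plan <- single_point_plan(params)
  rows <- lapply(w_b_values, function(wb) {
    ph <- phantom
    ph$thermal$w_b <- array(wb, dim(phantom$lesion_mask))
    res <- simulate_treatment(plan, params, ph, template = template)
    data.frame(w_b = wb, peak_T_C = res$peak_T,
               peak_cem43_min = res$peak_cem43,
               ablated_cm3 = res$ablated_cm3)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
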