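# File interfaces: cohort CSV, treatment-plan CSV, gridded field export to
# NIfTI, and YAML simulation configs.

#' Read / write a participant cohort as long-format CSV
#'
#' Columns: id, group, anesthesia, timepoint, L, W, H, npv, dii,
#' dysmenorrhea, menorrhagia.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a `hifu_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "timepoint", "L", "W", "H", "npv", "dii")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  class(x) <- c("hifu_cohort", "data.frame")
  x
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a treatment plan as CSV (order, x, y, z)
#' @param path CSV file path.
#' @return `read_plan()` returns a `treatment_plan` data.frame.
#' @export
read_plan <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("order", "x", "y", "z") %in% names(x)))
  x <- x[order(x$order), ]
  class(x) <- c("treatment_plan", "data.frame")
  x
}

#' @rdname read_plan
#' @param plan a `treatment_plan`.
#' @export
write_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan)[, c("order", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a gridded field to NIfTI volumes
#'
#' Complex pressure fields are written as separate magnitude and phase
#' volumes; intensity, temperature and dose fields as single volumes. Grid
#' spacing is carried in the NIfTI pixdim. Axial convention: the third axis
#' is the beam axis, increasing away from the transducer.
#'
#' @param field a `pressure_field`, `intensity_field`, or `dose_field` with
#'   grid coordinates.
#' @param prefix output path prefix (files get `_mag`/`_phase` or `.nii`
#'   suffixes).
#' @param spacing voxel spacing, mm; inferred from coordinates when present.
#' @return invisibly, the written file path(s).
#' @export
write_field_nifti <- function(field, prefix, spacing = NULL) {
  if (is.null(spacing) && !is.null(field$x)) spacing <- field$x[2] - field$x[1]
  if (is.null(spacing)) stop("voxel spacing is required")
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(spacing, 3)
    RNifti::writeNifti(img, path)
    path
  }
  if (!is.null(field$p)) {
    paths <- c(wr(abs(field$p), paste0(prefix, "_mag.nii.gz")),
               wr(Arg(field$p), paste0(prefix, "_phase.nii.gz")))
  } else if (!is.null(field$I)) {
    paths <- wr(field$I, paste0(prefix, "_intensity.nii.gz"))
  } else if (!is.null(field$cem43)) {
    paths <- wr(field$cem43, paste0(prefix, "_cem43.nii.gz"))
  } else stop("unsupported field object")
  invisible(paths)
}

#' Read a simulation configuration from YAML
#'
#' Recognized blocks: `transducer` (focal_length, aperture_radius,
#' center_frequency, max_subelement), `layers` (list of beam-path layers),
#' `grid` (spacing, lateral_halfwidth, z_min, z_max), `phantom` (domain,
#' voxel, lesion_semiaxes, scenario) and `parameters` (a preset label or the
#' seven protocol values). Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return a list with any of `geometry`, `path`, `grid`, `phantom`,
#'   `params`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$transducer)) {
    tr <- cfg$transducer
    out$geometry <- discretize_bowl(
      tr$focal_length %||% 130, tr$aperture_radius %||% 64,
      tr$center_frequency %||% 1,
      max_subelement = tr$max_subelement)
  }
  if (!is.null(cfg$layers)) {
    out$path <- beam_path(do.call(rbind, lapply(cfg$layers, as.data.frame)))
  }
  if (!is.null(cfg$grid)) out$grid <- cfg$grid
  if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    out$phantom <- generate_phantom(
      domain = unlist(ph$domain %||% c(40, 40, 40)),
      voxel = ph$voxel %||% 0.5,
      lesion_semiaxes = unlist(ph$lesion_semiaxes %||% c(10, 10, 10)),
      scenario = ph$scenario %||% "adenomyosis-myometrium")
  }
  if (!is.null(cfg$parameters)) {
    pp <- cfg$parameters
    out$params <- if (is.character(pp)) sonication_preset(pp)
    else sonication_params(pp$point_interval, pp$focal_intensity,
                           pp$duty_cycle, pp$center_frequency %||% 1,
                           pp$prf %||% 10, pp$per_point_time,
                           pp$transition_time, label = pp$label %||% "custom")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
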