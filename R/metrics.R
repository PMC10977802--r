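# Clinical efficacy indices and cohort descriptive summaries.
#
# Volumes in cm3, axis lengths in cm, ratios reported in percent. Internal
# values keep full precision; round_half_out() is applied only when tables
# are printed.

#' Ellipsoid lesion volume from three orthogonal axis lengths
#'
#' `0.523 * length * width * height` (0.523 approximates pi/6 on full axis
#' lengths), the standard MRI estimate of an ellipsoidal lesion volume.
#'
#' @param L,W,H axis lengths, cm. Vectorized.
#' @return volume, cm3.
#' @examples
#' ellipsoid_volume(5.7, 5.1, 4.0)  # 60.81 cm3
#' @export
ellipsoid_volume <- function(L, W, H) {
  if (any(c(L, W, H) < 0, na.rm = TRUE)) stop("axis lengths must be >= 0")
  0.523 * L * W * H
}

#' Adenomyosis volume shrinkage ratio (AVSR)
#'
#' `100 * (1 - v_after / v_before)` percent; negative values indicate
#' growth.
#'
#' @param v_before baseline lesion volume, cm3 (> 0).
#' @param v_after follow-up lesion volume, cm3 (>= 0). Vectorized.
#' @return shrinkage ratio, percent.
#' @examples
#' avsr(60.8, 12.0)  # 80.26 -> printed as 80.3
#' @export
avsr <- function(v_before, v_after) {
  if (any(v_before <= 0, na.rm = TRUE))
    stop("baseline volume must be positive")
  if (any(v_after < 0, na.rm = TRUE))
    stop("follow-up volume must be non-negative")
  100 * (1 - v_after / v_before)
}

#' Nonperfused volume ratio (NPVR)
#'
#' Nonperfused (unenhancing) volume divided by a reference lesion volume, in
#' percent. The defining reference is the original (baseline) lesion volume;
#' a same-timepoint reference is also used in practice and both are
#' supported — the caller selects which volume to pass.
#'
#' @param nonperfused_volume cm3, >= 0.
#' @param reference_volume cm3, > 0.
#' @return ratio, percent. Vectorized.
#' @examples
#' npvr(8.3, 12.0)   # same-timepoint reference
#' npvr(8.3, 60.8)   # original-volume reference
#' @export
npvr <- function(nonperfused_volume, reference_volume) {
  if (any(reference_volume <= 0, na.rm = TRUE))
    stop("reference volume must be positive")
  if (any(nonperfused_volume < 0, na.rm = TRUE))
    stop("nonperfused volume must be non-negative")
  100 * nonperfused_volume / reference_volume
}

#' Clinically effective dysmenorrhea improvement index
#'
#' The DII is an ordinal 1-5 scale (1 complete relief, 2 partial, 3 minor,
#' 4 ineffective, 5 exacerbated); a score of 3 or less is defined as
#' clinically effective.
#'
#' @param score integer DII score(s) in 1..5; NA passes through.
#' @return logical vector.
#' @examples
#' dii_effective(c(1, 3, 4))
#' @export
dii_effective <- function(score) {
  ok <- is.na(score) | (score %in% 1:5)
  if (!all(ok)) stop("DII scores must lie in {1, ..., 5}")
  score <= 3
}

q13 <- function(x) stats::quantile(x, c(.25, .75), type = 7, names = FALSE)

#' Descriptive cohort summaries by group and timepoint
#'
#' Computes, per group x timepoint, medians and quartiles (type-7 linear
#' interpolation) of the continuous indices — lesion volume, nonperfused
#' volume, NPVR, AVSR — and the proportion of clinically effective DII with
#' its counts. Analyses are complete-case per cell; cells with no data are
#' flagged missing (`n = 0`, `NA` values), never zero.
#'
#' @param cohort a long-format cohort data.frame as produced by
#'   [generate_cohort()] or [read_cohort()]: columns `id`, `group`,
#'   `timepoint`, `L`, `W`, `H`, `npv`, `dii` (and optionally others).
#' @param npvr_reference `"original"` (baseline lesion volume, the defining
#'   denominator) or `"same_timepoint"`.
#' @return a `cohort_summary`: list with data.frames `continuous`
#'   (group, timepoint, variable, n, median, q1, q3, missing) and
#'   `effective_dii` (group, timepoint, n_effective, n, percent, counts).
#' @export
summarize_cohort <- function(cohort,
                             npvr_reference = c("original",
                                                "same_timepoint")) {
  npvr_reference <- match.arg(npvr_reference)
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop("empty cohort")
  tp_levels <- c("screening", "immediate", "1m", "3m", "1y", "3y")
  cohort$timepoint <- factor(cohort$timepoint, levels = tp_levels)
  cohort$volume <- ellipsoid_volume(cohort$L, cohort$W, cohort$H)
  base <- cohort[cohort$timepoint == "screening", c("id", "volume")]
  names(base)[2] <- "baseline_volume"
  cohort <- merge(cohort, base, by = "id", all.x = TRUE, sort = FALSE)
  ref <- if (npvr_reference == "original") cohort$baseline_volume
  else cohort$volume
  cohort$npvr <- ifelse(!is.na(cohort$npv) & !is.na(ref) & ref > 0,
                        100 * cohort$npv / ref, NA_real_)
  cohort$avsr <- ifelse(cohort$timepoint %in% c("1m", "3m") &
                          !is.na(cohort$volume) &
                          !is.na(cohort$baseline_volume),
                        100 * (1 - cohort$volume / cohort$baseline_volume),
                        NA_real_)
  groups <- sort(unique(as.character(cohort$group)))
  vars <- c("volume", "npv", "npvr", "avsr")
  cont <- expand.grid(group = groups, timepoint = tp_levels,
                      variable = vars, stringsAsFactors = FALSE)
  stats_row <- function(g, tp, v) {
    x <- cohort[[v]][cohort$group == g & cohort$timepoint == tp]
    x <- x[!is.na(x)]
    if (length(x) == 0) c(0, NA, NA, NA) else c(length(x), stats::median(x),
                                                q13(x))
  }
  m <- t(mapply(stats_row, cont$group, cont$timepoint, cont$variable))
  cont$n <- as.integer(m[, 1]); cont$median <- m[, 2]
  cont$q1 <- m[, 3]; cont$q3 <- m[, 4]
  cont$missing <- cont$n == 0L
  cont <- cont[cont$n > 0 | cont$timepoint %in%
                 unique(as.character(cohort$timepoint)), ]
  rownames(cont) <- NULL
  dii_rows <- expand.grid(group = groups,
                          timepoint = c("1m", "3m", "1y", "3y"),
                          stringsAsFactors = FALSE)
  eff <- t(mapply(function(g, tp) {
    s <- cohort$dii[cohort$group == g & cohort$timepoint == tp]
    s <- s[!is.na(s)]
    c(sum(dii_effective(s)), length(s))
  }, dii_rows$group, dii_rows$timepoint))
  dii_rows$n_effective <- as.integer(eff[, 1])
  dii_rows$n <- as.integer(eff[, 2])
  dii_rows$percent <- ifelse(dii_rows$n > 0,
                             100 * dii_rows$n_effective / dii_rows$n, NA)
  dii_rows$counts <- ifelse(dii_rows$n > 0,
                            sprintf("%d/%d", dii_rows$n_effective,
                                    dii_rows$n), NA)
  rownames(dii_rows) <- NULL
  structure(list(continuous = cont, effective_dii = dii_rows,
                 npvr_reference = npvr_reference),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (medians [Q1-Q3], NPVR reference:",
      x$npvr_reference, ")\n\n")
  cc <- x$continuous[x$continuous$n > 0, ]
  cc$cell <- sprintf("%s (%s-%s)", round_half_out(cc$median),
                     round_half_out(cc$q1), round_half_out(cc$q3))
  print(cc[, c("group", "timepoint", "variable", "n", "cell")],
        row.names = FALSE)
  cat("\nClinically effective DII (percent (n/N)):\n")
  dd <- x$effective_dii[x$effective_dii$n > 0, ]
  dd$cell <- sprintf("%s (%s)", round_half_out(dd$percent), dd$counts)
  print(dd[, c("group", "timepoint", "cell")], row.names = FALSE)
  invisible(x)
}
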