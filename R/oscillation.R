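#' Oscillation classification thresholds
#'
#' The experimental literature rarely states a formal sustained/damped
#' criterion, so this package fixes one and logs it with every result:
#' a signal is *sustained* if, after discarding the transient, at least
#' `min_peaks` local maxima remain and the mean per-cycle amplitude ratio is
#' at least `decay_ratio`; *damped* if maxima exist but decay faster; *none*
#' otherwise. Cycles whose mean amplitude falls below `min_amplitude_rel`
#' times the post-transient signal range are treated as numerical ripple, not
#' oscillation.
#'
#' @param decay_ratio minimum amplitude ratio per cycle for "sustained"
#'   (default 0.95).
#' @param min_peaks minimum number of post-transient maxima (default 3).
#' @param min_amplitude_rel amplitude floor relative to the signal range
#'   (default 0.01).
#' @return named list of thresholds.
#' @export
oscillation_thresholds <- function(decay_ratio = 0.95, min_peaks = 3L,
                                   min_amplitude_rel = 0.01) {
  list(decay_ratio = decay_ratio, min_peaks = as.integer(min_peaks),
       min_amplitude_rel = min_amplitude_rel)
}

# Local maxima with parabolic sub-sample refinement. Returns a data.frame of
# refined times/heights plus trough information for amplitude tracking.
find_peaks <- function(t, x) {
  n <- length(x)
  if (n < 3) return(list(peaks = numeric(0), heights = numeric(0),
                         troughs = numeric(0), depths = numeric(0)))
  core <- 2:(n - 1)
  is_max <- x[core] > x[core - 1] & x[core] >= x[core + 1]
  is_min <- x[core] < x[core - 1] & x[core] <= x[core + 1]
  refine <- function(i) {
    # vertex of the parabola through the three points around i
    t1 <- t[i - 1]; t2 <- t[i]; t3 <- t[i + 1]
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    denom <- (t1 - t2) * (t1 - t3) * (t2 - t3)
    a <- (t3 * (y2 - y1) + t2 * (y1 - y3) + t1 * (y3 - y2)) / denom
    b <- (t3^2 * (y1 - y2) + t2^2 * (y3 - y1) + t1^2 * (y2 - y3)) / denom
    if (a == 0) return(c(t2, y2))
    tv <- -b / (2 * a)
    if (tv < t1 || tv > t3) return(c(t2, y2))
    cc <- y2 - a * t2^2 - b * t2
    c(tv, a * tv^2 + b * tv + cc)
  }
  pk <- core[is_max]
  tr <- core[is_min]
  pk_ref <- vapply(pk, refine, numeric(2))
  tr_ref <- vapply(tr, refine, numeric(2))
  list(peaks = if (length(pk)) pk_ref[1, ] else numeric(0),
       heights = if (length(pk)) pk_ref[2, ] else numeric(0),
       troughs = if (length(tr)) tr_ref[1, ] else numeric(0),
       depths = if (length(tr)) tr_ref[2, ] else numeric(0))
}

# Shared analysis: peaks, period, amplitude and per-cycle decay of one
# species' signal after discarding the initial transient fraction.
analyze_oscillation <- function(traj, species, transient_fraction = 0.3,
                                thresholds = oscillation_thresholds()) {
  t <- traj$times
  x <- traj$states[, species]
  t_cut <- t[1] + transient_fraction * (t[length(t)] - t[1])
  keep <- t >= t_cut
  t <- t[keep]; x <- x[keep]
  fp <- find_peaks(t, x)
  unit_h <- time_unit_seconds(traj$time_unit) / 3600
  res <- list(n_peaks = length(fp$peaks), period_h = NA_real_,
              amplitude = NA_real_, decay_ratio = NA_real_,
              transient_fraction = transient_fraction,
              thresholds = thresholds, species = species)
  if (length(fp$peaks) < max(2L, thresholds$min_peaks)) {
    res$class <- "none"
    return(res)
  }
  res$period_h <- mean(diff(fp$peaks)) * unit_h
  # amplitude of each cycle: peak height minus the next trough
  amps <- vapply(seq_along(fp$peaks), function(i) {
    nxt <- fp$troughs[fp$troughs > fp$peaks[i]]
    if (!length(nxt)) return(NA_real_)
    j <- which(fp$troughs == nxt[1])[1]
    fp$heights[i] - fp$depths[j]
  }, 0)
  amps <- amps[is.finite(amps) & amps > 0]
  rng <- diff(range(x))
  if (length(amps) < 2 || rng <= 0 ||
      mean(amps) < thresholds$min_amplitude_rel * rng) {
    res$class <- "none"
    res$period_h <- NA_real_
    return(res)
  }
  res$amplitude <- mean(amps)
  ratios <- amps[-1] / amps[-length(amps)]
  res$decay_ratio <- exp(mean(log(ratios)))
  res$class <- if (res$decay_ratio >= thresholds$decay_ratio)
    "sustained" else "damped"
  res
}

#' Estimate the oscillation period of a trajectory
#'
#' Mean peak-to-peak interval of the local maxima of one species'
#' concentration, after discarding an initial transient and with parabolic
#' sub-sample refinement of each peak time. Always reported in hours,
#' whatever the trajectory's declared unit.
#'
#' @param traj a [trajectory()].
#' @param species species index or name.
#' @param transient_fraction initial fraction of the horizon to discard
#'   (default 0.3; early cycles are atypical while the reactor phase-locks).
#' @return period in hours, or `NA` when fewer than 3 post-transient maxima
#'   exist (a "no period" result, not an error).
#' @export
estimate_period <- function(traj, species, transient_fraction = 0.3) {
  if (is.character(species)) species <- match(species, colnames(traj$states))
  analyze_oscillation(traj, species, transient_fraction)$period_h
}

#' Classify a trajectory as sustained, damped or non-oscillating
#'
#' @inheritParams estimate_period
#' @param thresholds an [oscillation_thresholds()] list; always attached to
#'   the result so every classification is reproducible.
#' @return character class `"sustained"`, `"damped"` or `"none"`, with the
#'   full analysis (period, amplitude, decay ratio, thresholds) as attribute
#'   `"analysis"`.
#' @export
classify_oscillation <- function(traj, species, transient_fraction = 0.3,
                                 thresholds = oscillation_thresholds()) {
  if (is.character(species)) species <- match(species, colnames(traj$states))
  a <- analyze_oscillation(traj, species, transient_fraction, thresholds)
  structure(a$class, analysis = a)
}

#' Scan the oscillation space over inflow concentrations
#'
#' Solves the model once per grid cell of the Cartesian product of inflow
#' Fmoc-piperidine and phenyl acetate concentrations and summarizes each cell
#' (class, period, amplitude). A trained correction, when supplied, is reused
#' unchanged across all cells: the learned dynamics are transferred between
#' experimental settings rather than retrained.
#'
#' @param network a [crn_network()].
#' @param fmoc_grid,pa_grid inflow concentration axes (M).
#' @param flow_template [flow_conditions()] providing the dilution rate and
#'   the inflow entries of all other species.
#' @param y0 reactor start-up state.
#' @param horizon solve horizon in the network's time unit; should cover >= 10
#'   expected periods past the transient.
#' @param correction optional trained [init_correction()] (the nODE scan).
#' @param species species whose signal is analyzed (default 6,
#'   dibenzofulvene).
#' @param axis_species indices of the two scanned inflow species (default
#'   `c(2, 4)`).
#' @param save_dt save-grid spacing (default 0.05 time units).
#' @param config a [solver_config()].
#' @param transient_fraction,thresholds passed to the per-cell analysis.
#' @return a `phase_diagram`: data.frame with columns `fmoc_in_M`, `pa_in_M`,
#'   `class`, `period_h`, `amplitude`, `decay_ratio`, `flag` (solver failure),
#'   with the grids, thresholds and model tag as attributes.
#' @export
scan_phase_space <- function(network, fmoc_grid, pa_grid, flow_template, y0,
                             horizon, correction = NULL, species = 6L,
                             axis_species = c(2L, 4L), save_dt = 0.05,
                             config = solver_config(),
                             transient_fraction = 0.3,
                             thresholds = oscillation_thresholds()) {
  stopifnot(length(fmoc_grid) >= 1, length(pa_grid) >= 1)
  save_times <- seq(0, horizon, by = save_dt)
  jac <- augmented_jacobian(network, correction, NULL)  # D added per cell
  cells <- vector("list", length(fmoc_grid) * length(pa_grid))
  idx <- 0L
  for (pa in pa_grid) for (fm in fmoc_grid) {
    idx <- idx + 1L
    y_in <- flow_template$y_in
    y_in[axis_species[1]] <- fm
    y_in[axis_species[2]] <- pa
    fl <- flow_conditions(y_in, flow_template$D)
    rhs <- if (is.null(correction)) apply_flow(build_rhs(network), fl)
           else augmented_rhs(network, correction, fl)
    jc <- augmented_jacobian(network, correction, fl)
    tr <- try(solve_ivp(rhs, y0, save_times, config = config,
                        species = network$species$name,
                        time_unit = network$time_unit, jac = jc),
              silent = TRUE)
    if (inherits(tr, "try-error")) {
      cells[[idx]] <- data.frame(fmoc_in_M = fm, pa_in_M = pa,
                                 class = "none", period_h = NA_real_,
                                 amplitude = NA_real_,
                                 decay_ratio = NA_real_, flag = TRUE)
      next
    }
    a <- analyze_oscillation(tr, species, transient_fraction, thresholds)
    cells[[idx]] <- data.frame(fmoc_in_M = fm, pa_in_M = pa, class = a$class,
                               period_h = a$period_h,
                               amplitude = a$amplitude,
                               decay_ratio = a$decay_ratio, flag = FALSE)
  }
  out <- do.call(rbind, cells)
  attr(out, "fmoc_grid") <- fmoc_grid
  attr(out, "pa_grid") <- pa_grid
  attr(out, "thresholds") <- thresholds
  attr(out, "transient_fraction") <- transient_fraction
  attr(out, "model") <- if (is.null(correction)) "theory" else "node"
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> model:", attr(x, "model"), "-",
      length(attr(x, "fmoc_grid")), "x", length(attr(x, "pa_grid")),
      "grid;", sum(x$class == "sustained"), "sustained,",
      sum(x$class == "damped"), "damped,", sum(x$class == "none"), "none\n")
  invisible(x)
}

#' Difference between two predicted oscillation spaces
#'
#' Per-cell period difference `a - b`, defined only where both diagrams
#' predict sustained oscillations; elsewhere `NA`.
#'
#' @param a,b two `phase_diagram`s on identical grids.
#' @return data.frame with `fmoc_in_M`, `pa_in_M`, `dperiod_h`.
#' @export
diff_phase_diagrams <- function(a, b) {
  if (!isTRUE(all.equal(attr(a, "fmoc_grid"), attr(b, "fmoc_grid"))) ||
      !isTRUE(all.equal(attr(a, "pa_grid"), attr(b, "pa_grid"))) ||
      !identical(a$fmoc_in_M, b$fmoc_in_M) ||
      !identical(a$pa_in_M, b$pa_in_M))
    stop("phase diagrams are on different grids")
  both <- a$class == "sustained" & b$class == "sustained"
  data.frame(fmoc_in_M = a$fmoc_in_M, pa_in_M = a$pa_in_M,
             dperiod_h = ifelse(both, a$period_h - b$period_h, NA_real_))
}

#' Periods of several models across experimental settings
#'
#' One flow solve per (model, setting); mirrors the usual
#' observed-versus-predicted period tables.
#'
#' @param models named list; each element is either a [crn_network()] or a
#'   list `list(network =, correction =)`.
#' @param settings data.frame with columns `fmoc_in_M` and `pa_in_M`.
#' @param flow_template,y0,horizon,species,axis_species,save_dt,config,
#'   transient_fraction as in [scan_phase_space()].
#' @return data.frame: the settings columns followed by one period column
#'   (hours) per model.
#' @export
period_table <- function(models, settings, flow_template, y0, horizon,
                         species = 6L, axis_species = c(2L, 4L),
                         save_dt = 0.05, config = solver_config(),
                         transient_fraction = 0.3) {
  stopifnot(is.list(models), !is.null(names(models)),
            all(c("fmoc_in_M", "pa_in_M") %in% names(settings)))
  out <- settings[, c("fmoc_in_M", "pa_in_M")]
  for (nm in names(models)) {
    m <- models[[nm]]
    if (inherits(m, "crn_network")) m <- list(network = m, correction = NULL)
    periods <- vapply(seq_len(nrow(settings)), function(i) {
      pd <- scan_phase_space(m$network, settings$fmoc_in_M[i],
                             settings$pa_in_M[i], flow_template, y0, horizon,
                             correction = m$correction, species = species,
                             axis_species = axis_species, save_dt = save_dt,
                             config = config,
                             transient_fraction = transient_fraction)
      pd$period_h[1]
    }, 0)
    out[[nm]] <- periods
  }
  out
}
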