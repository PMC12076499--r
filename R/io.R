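# File formats. All numeric CSV output is printed with %.17g so doubles
# round-trip bit-identically; time columns are named time_<unit> with the
# unit parsed back on read.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_num_csv <- function(df, path) {
  chr <- vapply(df, function(col)
    if (is.numeric(col)) list(fmt_num(col)) else list(as.character(col)),
    vector("list", 1))
  out <- do.call(cbind, lapply(chr, identity))
  colnames(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

parse_time_unit <- function(header) {
  m <- regmatches(header, regexec("^time_([a-z]+)$", header))[[1]]
  if (length(m) < 2) stop("first column must be named time_<unit>, got '",
                          header, "'")
  match.arg(m[2], c("s", "h", "d"))
}

#' Write / read a measurement series as CSV
#'
#' Columns: `time_<unit>`, then `<species>_mean` for every species and
#' `<species>_std` for measured species only (the presence of a std column is
#' what marks a species as measured). Values are written in full precision, so
#' a write/read cycle is lossless.
#'
#' @param ms a [measurement_series()].
#' @param path file path.
#' @return `write_measurements` returns `path` invisibly;
#'   `read_measurements` returns a [measurement_series()].
#' @export
write_measurements <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_series"))
  sp <- colnames(ms$mean)
  if (is.null(sp)) sp <- paste0("species", seq_len(ncol(ms$mean)))
  df <- data.frame(time = ms$times)
  names(df) <- paste0("time_", ms$time_unit)
  for (k in seq_along(sp)) df[[paste0(sp[k], "_mean")]] <- ms$mean[, k]
  for (k in ms$measured) df[[paste0(sp[k], "_std")]] <- ms$std[, k]
  write_num_csv(df, path)
  invisible(path)
}

#' @rdname write_measurements
#' @param time_unit optional target unit; when it differs from the file's
#'   header unit the time column is converted (concentrations are unchanged).
#' @export
read_measurements <- function(path, time_unit = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty measurement file: ", path)
  unit <- parse_time_unit(names(df)[1])
  times <- df[[1]]
  if (any(diff(times) <= 0)) stop("non-monotone times in ", path)
  mean_cols <- grep("_mean$", names(df), value = TRUE)
  if (!length(mean_cols)) stop("no <species>_mean columns in ", path)
  sp <- sub("_mean$", "", mean_cols)
  M <- length(sp)
  mean <- as.matrix(df[mean_cols]); colnames(mean) <- sp
  std <- matrix(0, nrow(df), M, dimnames = list(NULL, sp))
  measured <- integer(0)
  for (k in seq_len(M)) {
    sc <- paste0(sp[k], "_std")
    if (sc %in% names(df)) {
      std[, k] <- df[[sc]]
      measured <- c(measured, k)
    }
  }
  if (!length(measured)) {
    warning("no _std columns found; treating every species as measured with std 0")
    measured <- seq_len(M)
  }
  if (!is.null(time_unit) && time_unit != unit) {
    times <- times * time_unit_seconds(unit) / time_unit_seconds(time_unit)
    unit <- time_unit
  }
  measurement_series(times, mean, std, measured, time_unit = unit)
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_<unit>` then one column per species.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory` a
#'   [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  sp <- colnames(traj$states)
  if (is.null(sp)) sp <- paste0("species", seq_len(ncol(traj$states)))
  df <- data.frame(time = traj$times)
  names(df) <- paste0("time_", traj$time_unit)
  for (k in seq_along(sp)) df[[sp[k]]] <- traj$states[, k]
  write_num_csv(df, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty trajectory file: ", path)
  unit <- parse_time_unit(names(df)[1])
  trajectory(df[[1]], as.matrix(df[-1]), species = names(df)[-1],
             time_unit = unit)
}

#' Save / load a correction-network checkpoint
#'
#' JSON with the architecture (`n_io`, hidden size, measured indices, scaling
#' constants, seed) and all parameters at full precision.
#'
#' @param correction a [init_correction()] object.
#' @param path file path (conventionally `.json`).
#' @return `save_correction` returns `path` invisibly; `load_correction` the
#'   restored `neural_correction`.
#' @export
save_correction <- function(correction, path) {
  stopifnot(inherits(correction, "neural_correction"))
  obj <- list(format = "crnode_correction", version = 1L,
              n_io = correction$n_io, hidden = correction$hidden,
              measured = correction$measured, seed = correction$seed,
              x_scale = correction$x_scale,
              out_scale = correction$out_scale,
              W = as.vector(correction$W), U = as.vector(correction$U),
              b = correction$b, V = as.vector(correction$V),
              c0 = correction$c0)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_correction
#' @export
load_correction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "crnode_correction"))
    stop(path, " is not a crnode correction checkpoint")
  n <- obj$n_io; H <- obj$hidden
  corr <- init_correction(n, H, seed = obj$seed, measured = obj$measured,
                          x_scale = obj$x_scale,
                          out_scale = if (!is.null(obj$out_scale))
                            obj$out_scale else rep(1, n))
  corr$W <- matrix(obj$W, 4 * H, n)
  corr$U <- matrix(obj$U, 4 * H, H)
  corr$b <- as.numeric(obj$b)
  corr$V <- matrix(obj$V, n, H)
  corr$c0 <- as.numeric(obj$c0)
  corr
}

#' Read a reaction network from a YAML file
#'
#' Layout: `time_unit`; `species` (list of `index`/`name`/`constant`);
#' `reactions` (list of `label`, `rate_constant`, `reactants`, `products`,
#' optional `exponents` maps keyed by species name); `kappa` (named map);
#' optional `flow` block (`D`, `y_in` as a map keyed by species name or a
#' vector).
#'
#' @param path YAML file.
#' @return list with `network` (a [crn_network()]) and `flow`
#'   (a [flow_conditions()] or `NULL`).
#' @export
read_network <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (fld in c("species", "reactions", "kappa"))
    if (is.null(cfg[[fld]])) stop("network file misses field '", fld, "'")
  sp <- do.call(rbind, lapply(cfg$species, function(s)
    data.frame(index = s$index, name = s$name,
               constant = isTRUE(s$constant))))
  rx <- lapply(cfg$reactions, function(r) {
    reaction(unlist(r$reactants), unlist(r$products),
             rate_constant = r$rate_constant,
             exponents = if (!is.null(r$exponents)) unlist(r$exponents),
             label = if (!is.null(r$label)) r$label else r$rate_constant)
  })
  net <- crn_network(sp, rx, unlist(cfg$kappa),
                     time_unit = if (!is.null(cfg$time_unit)) cfg$time_unit
                                 else "h")
  flow <- NULL
  if (!is.null(cfg$flow)) {
    y_in <- numeric(nrow(sp))
    yi <- cfg$flow$y_in
    if (!is.null(names(yi))) {
      idx <- match(names(yi), sp$name)
      if (anyNA(idx)) stop("unknown species in flow y_in")
      y_in[idx] <- unlist(yi)
    } else {
      y_in <- unlist(yi)
    }
    flow <- flow_conditions(y_in, cfg$flow$D)
  }
  list(network = net, flow = flow)
}

#' Export a phase diagram as CSV
#'
#' Columns `fmoc_in_M, pa_in_M, class, period_h, amplitude, decay_ratio,
#' flag`. The CSV stays plain; the classification thresholds are recorded in
#' the run log instead.
#'
#' @param pd a `phase_diagram` from [scan_phase_space()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_phase_diagram <- function(pd, path) {
  write_num_csv(as.data.frame(pd), path)
  invisible(path)
}

# Append one JSON-lines record to the run log.
log_jsonl <- function(dir, record) {
  path <- file.path(dir, "run_log.jsonl")
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA,
                           null = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
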