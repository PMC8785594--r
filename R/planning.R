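# Clinical planning chain: certificate-based absolute calibration, dose
# rates at the six reference positions, the distance sweep, placement
# selection under the staphyloma constraint, prescription time and
# delivered doses.

#' Manufacturer-style depth-dose certificate
#'
#' @param reference_depth central-axis depth of the certified absolute dose
#'   rate, mm.
#' @param reference_dose_rate certified dose rate at the reference depth,
#'   mGy/min.
#' @param depth_mm,dose_rate the certified depth-dose table (mm, mGy/min).
#' @return object of class `certificate`.
#' @export
certificate_data <- function(reference_depth, reference_dose_rate,
                             depth_mm, dose_rate) {
  if (reference_dose_rate <= 0 || any(dose_rate <= 0)) {
    stop_invalid("certificate dose rates must be positive")
  }
  if (is.unsorted(depth_mm, strictly = TRUE)) {
    stop_invalid("certificate depths must be strictly ascending")
  }
  structure(list(reference_depth = reference_depth,
                 reference_dose_rate = reference_dose_rate,
                 table = data.frame(depth_mm = depth_mm,
                                    dose_rate = dose_rate)),
            class = "certificate")
}

#' @export
print.certificate <- function(x, ...) {
  cat(sprintf("certificate: %.1f mGy/min at %.1f mm depth, %d table rows\n",
              x$reference_dose_rate, x$reference_depth, nrow(x$table)))
  invisible(x)
}

#' Write / read a certificate file
#'
#' Plain-text format: `#`-prefixed header lines naming the reference depth
#' and dose rate, then a TSV depth-dose table.
#'
#' @param cert a `certificate`.
#' @param path file path.
#' @export
write_certificate <- function(cert, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# reference_depth_mm: %.6g", cert$reference_depth),
               sprintf("# reference_dose_rate_mGy_min: %.8g",
                       cert$reference_dose_rate),
               "depth_mm\tdose_rate_mGy_min"), con)
  utils::write.table(cert$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_certificate
#' @export
read_certificate <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(key, hdr, value = TRUE)
    if (length(m) != 1) stop_invalid("certificate header missing %s", key)
    as.numeric(sub(".*:\\s*", "", m))
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  certificate_data(getv("reference_depth_mm"),
                   getv("reference_dose_rate_mGy_min"),
                   tab[[1]], tab[[2]])
}

# interpolate a depth-dose curve (Gy/decay) at a depth
depth_curve_at <- function(curve, depth) {
  if (depth < min(curve$depth_mm) || depth > max(curve$depth_mm)) {
    stop_invalid("depth %.2f mm outside the simulated curve", depth)
  }
  stats::approx(curve$depth_mm, curve$value, depth)$y
}

#' Calibrate simulated dose-per-decay to absolute dose rate
#'
#' The scale factor (effective decays per minute) that maps the simulated
#' central-axis dose per decay at the certificate's reference point to the
#' certified absolute dose rate.  Applying it makes the simulated rate at
#' the reference point equal the certificate exactly.
#'
#' @param sim a `dose_grid` (plaque mode, validation frame) or a
#'   `depth_dose_curve` in Gy per decay.
#' @param cert a `certificate`.
#' @param ... passed to [extract_depth_dose()] when `sim` is a grid.
#' @return scale factor, decays per minute.
#' @export
calibrate <- function(sim, cert, ...) {
  stopifnot(inherits(cert, "certificate"))
  curve <- if (inherits(sim, "dose_grid")) extract_depth_dose(sim, ...) else sim
  stopifnot(inherits(curve, "depth_dose_curve"))
  v <- depth_curve_at(curve, cert$reference_depth)
  if (!is.finite(v) || v <= 0) {
    stop_invalid("simulated dose at the reference point is zero")
  }
  cert$reference_dose_rate / (1000 * v)  # decays/min
}

#' Calibrated dose field
#'
#' Couples a dose-per-decay backend with a calibration scale so positions
#' can be evaluated in absolute dose rate.  `backend` is either a
#' `dose_grid` or a list `(plaque, placement, kernel)` for the
#' deterministic engine.
#'
#' @param backend backend object.
#' @param scale decays per minute from [calibrate()].
#' @param component dose component used for grid lookups.
#' @return object of class `calibrated_field`.
#' @export
calibrated_field <- function(backend, scale,
                             component = c("total", "beta", "gamma")) {
  component <- match.arg(component)
  type <- if (inherits(backend, "dose_grid")) "mc" else "kernel"
  structure(list(backend = backend, scale = scale, type = type,
                 component = component),
            class = "calibrated_field")
}

#' Dose rates at the reference positions
#'
#' @param field a `calibrated_field`.
#' @param positions a `reference_positions` matrix (or any n x 3 matrix).
#' @return data.frame: `position`, `rate_mGy_min`, `rel_unc`.
#' @export
position_dose_rates <- function(field, positions) {
  stopifnot(inherits(field, "calibrated_field"))
  pts <- unclass(positions)
  if (field$type == "mc") {
    g <- grid_interp(field$backend, pts, component = field$component)
    val <- g$value; unc <- g$rel_unc
  } else {
    b <- field$backend
    # positions sit near or beyond the cap edge, where oblique window
    # crossings dominate: use the obliquity-aware window model
    val <- cap_dose(b$plaque, b$placement, pts, b$kernel,
                    window_model = "curved")
    unc <- rep(0, length(val))
  }
  data.frame(position = seq_len(nrow(pts)),
             rate_mGy_min = 1000 * field$scale * val,
             rel_unc = unc)
}

#' Sweep the edge distance d
#'
#' Re-places the plaque for every `d`, evaluates the six reference
#' positions with the deterministic kernel backend, and tabulates absolute
#' dose rates.  Infeasible placements are flagged, not dropped.
#'
#' @param plaque a `plaque_model`.
#' @param eye an `eye_model`.
#' @param kernel a `point_kernel`.
#' @param scale calibration scale, decays per minute.
#' @param d_grid edge distances to evaluate, mm.
#' @param contact_angle_deg anterior-edge suture-site angle.
#' @return object of class `sweep_table`: data.frame with `d_mm`,
#'   `feasible`, `r1`..`r6` (mGy/min).
#' @export
sweep_distance <- function(plaque, eye, kernel, scale, d_grid = 0:4,
                           contact_angle_deg = 105) {
  positions <- locate_positions(eye)
  rows <- lapply(d_grid, function(d) {
    pl <- tryCatch(place_plaque(plaque, eye, d, contact_angle_deg),
                   ruplaque_infeasible = function(e) NULL)
    if (is.null(pl)) {
      return(data.frame(d_mm = d, feasible = FALSE, t(rep(NA_real_, 6))))
    }
    fld <- calibrated_field(list(plaque = plaque, placement = pl,
                                 kernel = kernel), scale)
    r <- position_dose_rates(fld, positions)$rate_mGy_min
    data.frame(d_mm = d, feasible = TRUE, t(r))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("d_mm", "feasible", paste0("r", 1:6))
  structure(out, class = c("sweep_table", "data.frame"))
}

#' Select the treatment placement from a sweep
#'
#' The smallest feasible edge distance satisfying the anatomical
#' constraint `d >= d_min` (minimal stand-off maximizes tumor-edge
#' coverage).
#'
#' @param sweep a `sweep_table`.
#' @param d_min minimum edge distance imposed by anatomy (e.g. posterior
#'   staphyloma), mm.
#' @return chosen `d`, mm.
#' @export
select_placement <- function(sweep, d_min = 2) {
  if (nrow(sweep) == 0) stop_invalid("empty sweep table")
  ok <- sweep$feasible & sweep$d_mm >= d_min - 1e-9
  if (!any(ok)) stop_infeasible("no feasible placement with d >= %.1f mm", d_min)
  min(sweep$d_mm[ok])
}

#' Time required to deliver the prescription
#'
#' @param prescription_dose Gy.
#' @param limiting_rate limiting (minimum coverage-position) dose rate,
#'   mGy/min.
#' @return required attachment time, hours (exact; reports round to 0.1 h).
#' @export
required_time <- function(prescription_dose, limiting_rate) {
  if (!is.finite(limiting_rate) || limiting_rate <= 0) {
    stop_invalid("limiting dose rate must be positive")
  }
  if (prescription_dose <= 0) stop_invalid("prescription dose must be positive")
  prescription_dose * 1000 / limiting_rate / 60
}

#' Dose delivered at a given rate over a given time
#'
#' @param rate dose rate, mGy/min.
#' @param time_h attachment time, hours.
#' @return delivered dose, Gy (exact; reports round to 0.1 Gy).
#' @export
delivered_dose <- function(rate, time_h) {
  if (any(rate < 0, na.rm = TRUE) || any(time_h < 0, na.rm = TRUE)) {
    stop_invalid("rate and time must be non-negative")
  }
  rate * time_h * 60 / 1000
}

#' Plan from explicit position dose rates
#'
#' The arithmetic chain of the clinical computation, decoupled from
#' transport: given dose rates at the six positions (a "printed-rates"
#' mode), determine the limiting coverage position, the required time for
#' the prescription, and delivered doses for the actual attachment time.
#'
#' @param rates numeric vector of position dose rates, mGy/min; names or
#'   order give positions 1..6 (missing positions allowed as `NA`).
#' @param prescription_dose Gy.
#' @param attach_time actual attachment duration, hours; defaults to the
#'   required time.
#' @param coverage_positions positions defining the prescription minimum
#'   (tumor coverage points; the optic-disc points 5-6 are evaluated, not
#'   prescribed to).
#' @param chosen_d optional edge distance to record, mm.
#' @return object of class `plan_result`.
#' @export
plan_from_rates <- function(rates, prescription_dose = 40,
                            attach_time = NULL, coverage_positions = 1:4,
                            chosen_d = NA_real_) {
  rates <- as.numeric(rates)
  cov <- rates[coverage_positions]
  if (all(is.na(cov))) stop_invalid("no coverage-position rates available")
  limiting <- coverage_positions[which.min(cov)]
  limiting_rate <- rates[limiting]
  t_req <- required_time(prescription_dose, limiting_rate)
  t_att <- if (is.null(attach_time)) t_req else attach_time
  structure(list(
    chosen_d = chosen_d,
    rates_mGy_min = rates,
    coverage_positions = coverage_positions,
    limiting_position = limiting,
    limiting_rate = limiting_rate,
    prescription_dose = prescription_dose,
    required_time_h = t_req,
    attach_time_h = t_att,
    delivered_Gy = delivered_dose(rates, t_att)
  ), class = "plan_result")
}

#' Full planning computation for a case
#'
#' Sweep, placement selection, prescription time and delivered doses.
#'
#' @param sweep a `sweep_table`.
#' @param d_min anatomical minimum edge distance, mm.
#' @param prescription_dose Gy.
#' @param attach_time hours (optional).
#' @param coverage_positions prescription minimum positions.
#' @return `plan_result` with the sweep attached.
#' @export
build_plan <- function(sweep, d_min = 2, prescription_dose = 40,
                       attach_time = NULL, coverage_positions = 1:4) {
  d <- select_placement(sweep, d_min)
  row <- sweep[sweep$d_mm == d, ]
  rates <- as.numeric(row[1, paste0("r", 1:6)])
  out <- plan_from_rates(rates, prescription_dose, attach_time,
                         coverage_positions, chosen_d = d)
  out$sweep <- sweep
  out$d_min <- d_min
  out
}

#' @export
print.plan_result <- function(x, ...) {
  cat("plaque placement plan\n")
  if (!is.na(x$chosen_d)) {
    cat(sprintf("  chosen edge distance d: %.1f mm\n", x$chosen_d))
  }
  r <- round_half_up(x$rates_mGy_min, 1)
  for (i in seq_along(r)) {
    if (!is.na(r[i])) {
      cat(sprintf("  position %d: %.1f mGy/min -> %.1f Gy delivered\n",
                  i, r[i], round_half_up(x$delivered_Gy[i], 1)))
    }
  }
  cat(sprintf("  limiting position: %d (%.1f mGy/min)\n",
              x$limiting_position, round_half_up(x$limiting_rate, 1)))
  cat(sprintf("  required time for %.0f Gy: %.1f h; attachment time: %.1f h\n",
              x$prescription_dose, round_half_up(x$required_time_h, 1),
              round_half_up(x$attach_time_h, 1)))
  invisible(x)
}

#' Tabular form of a plan report
#'
#' @param plan a `plan_result`.
#' @return data.frame with per-position rounded rates and delivered doses.
#' @export
plan_report_table <- function(plan) {
  data.frame(position = seq_along(plan$rates_mGy_min),
             rate_mGy_min = round_half_up(plan$rates_mGy_min, 1),
             delivered_Gy = round_half_up(plan$delivered_Gy, 1),
             limiting = seq_along(plan$rates_mGy_min) == plan$limiting_position)
}
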