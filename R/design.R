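#' Diel sampling design
#'
#' Describes the sampling clock of a diel time-course experiment: the sample
#' times in Zeitgeber Time (ZT, hours after dawn; negative values are before
#' dawn), the clock times of dawn and dusk, and the nominal cycle length.
#' The default design is 14 samples every 2 h starting 2 h before dawn
#' (ZT-2 ... ZT24) with dawn at 5:45 and dusk at 19:00, i.e. a photoperiod of
#' 13.25 h light in a 24-h cycle.
#'
#' @param n_timepoints number of samples (>= 4).
#' @param interval_h sampling interval in hours (> 0).
#' @param start_offset_h ZT of the first sample (negative = before dawn).
#' @param dawn_clock,dusk_clock clock times as `"H:MM"` strings; dusk must be
#'   after dawn and the light interval must be shorter than `period_h`.
#' @param period_h nominal cycle length in hours.
#' @return An object of class `diel_design`: a list with fields
#'   `sample_times_zt`, `dawn_clock`, `dusk_clock`, `photoperiod_h`,
#'   `period_h`, `interval_h`.
#' @examples
#' d <- diel_design()
#' d$photoperiod_h  # 13.25
#' @export
diel_design <- function(n_timepoints = 14, interval_h = 2, start_offset_h = -2,
                        dawn_clock = "5:45", dusk_clock = "19:00",
                        period_h = 24) {
  if (n_timepoints < 4) {
    rhythmod_stop("design", "need at least 4 time points")
  }
  if (interval_h <= 0) {
    rhythmod_stop("design", "sampling interval must be positive")
  }
  if (period_h <= 0) {
    rhythmod_stop("design", "period must be positive")
  }
  dawn <- parse_clock(dawn_clock)
  dusk <- parse_clock(dusk_clock)
  photoperiod <- dusk - dawn
  if (photoperiod <= 0) {
    rhythmod_stop("design", "dusk must be after dawn (positive photoperiod)")
  }
  if (photoperiod >= period_h) {
    rhythmod_stop("design", "photoperiod must be shorter than the period")
  }
  structure(list(
    sample_times_zt = start_offset_h + (seq_len(n_timepoints) - 1) * interval_h,
    dawn_clock = dawn_clock,
    dusk_clock = dusk_clock,
    photoperiod_h = photoperiod,
    period_h = period_h,
    interval_h = interval_h
  ), class = "diel_design")
}

# "H:MM" (24-h clock) -> fractional hours
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.double(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || anyNA(suppressWarnings(as.numeric(parts)))) {
    rhythmod_stop("design", sprintf("cannot parse clock time '%s'", x))
  }
  as.numeric(parts[1]) + as.numeric(parts[2]) / 60
}

#' @export
print.diel_design <- function(x, ...) {
  cat(sprintf(
    "diel design: %d time points (ZT%g..ZT%g, every %g h), dawn %s, dusk %s, photoperiod %g h / %g h cycle\n",
    length(x$sample_times_zt), min(x$sample_times_zt), max(x$sample_times_zt),
    x$interval_h, x$dawn_clock, x$dusk_clock, x$photoperiod_h, x$period_h
  ))
  invisible(x)
}

#' ZT column labels for a design ("ZT-2", "ZT00", ..., "ZT24")
#' @param design a [diel_design()].
#' @return character vector of labels, one per sample time.
#' @export
zt_labels <- function(design) {
  vapply(design$sample_times_zt, function(t) {
    if (t < 0) sprintf("ZT%g", t) else sprintf("ZT%02g", t)
  }, character(1))
}
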