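#' Voltage-clamp sweep and sweep-set containers
#'
#' A `clamp_sweep` holds one uniformly sampled trace (current in pA for
#' voltage clamp, membrane voltage in mV for current clamp) together with
#' its pulse geometry. A `sweep_set` groups sweeps recorded under one pulse
#' protocol with the cell capacitance used for density normalization.
#'
#' Recognized protocols: `iv_na`, `inact_na`, `recovery_na`, `late_na`,
#' `iv_cal`, `inact_cal`, `ik1`, `outward_k`, `ap`.
#'
#' @param time_ms Sample times (ms), uniformly spaced from 0.
#' @param current_pA Current samples (pA); for `ap` sweeps this carries the
#'   membrane voltage in mV instead.
#' @param test_potential_mV Test-pulse potential (mV).
#' @param holding_potential_mV Holding potential (mV).
#' @param pulse_start_ms,pulse_duration_ms Test-pulse window (ms).
#' @param prepulse_mV Conditioning-prepulse potential (inactivation
#'   protocols), or `NA`.
#' @param interval_ms P1-P2 coupling interval (recovery protocol), or `NA`.
#' @return A `clamp_sweep` list.
#' @export
clamp_sweep <- function(time_ms, current_pA, test_potential_mV,
                        holding_potential_mV, pulse_start_ms,
                        pulse_duration_ms, prepulse_mV = NA_real_,
                        interval_ms = NA_real_) {
  stopifnot_msg(length(time_ms) == length(current_pA),
                "time and current vectors must align")
  stopifnot_msg(length(time_ms) >= 4L, "sweep too short")
  dt <- diff(time_ms)
  stopifnot_msg(max(abs(dt - dt[1])) < 1e-6 * dt[1] + 1e-12,
                "sweep must be uniformly sampled")
  stopifnot_msg(pulse_start_ms >= time_ms[1] &&
                  pulse_start_ms + pulse_duration_ms <=
                    time_ms[length(time_ms)] + dt[1] / 2,
                "pulse window must lie inside the trace")
  structure(list(time_ms = time_ms, current_pA = current_pA,
                 test_potential_mV = test_potential_mV,
                 holding_potential_mV = holding_potential_mV,
                 pulse_start_ms = pulse_start_ms,
                 pulse_duration_ms = pulse_duration_ms,
                 prepulse_mV = prepulse_mV, interval_ms = interval_ms),
            class = "clamp_sweep")
}

CLAMP_PROTOCOLS <- c("iv_na", "inact_na", "recovery_na", "late_na",
                     "iv_cal", "inact_cal", "ik1", "outward_k", "ap")

#' @rdname clamp_sweep
#' @param sweeps List of `clamp_sweep` objects.
#' @param protocol Protocol name (see Details).
#' @param cell_capacitance_pF Cell capacitance (pF), > 0.
#' @export
sweep_set <- function(sweeps, protocol, cell_capacitance_pF) {
  protocol <- match.arg(protocol, CLAMP_PROTOCOLS)
  stopifnot_msg(is.list(sweeps) && length(sweeps) >= 1L &&
                  all(vapply(sweeps, inherits, logical(1), "clamp_sweep")),
                "sweeps must be a non-empty list of clamp_sweep objects")
  stopifnot_msg(cell_capacitance_pF > 0, "cell capacitance must be > 0")
  if (protocol %in% c("iv_na", "iv_cal", "ik1", "outward_k")) {
    vm <- vapply(sweeps, `[[`, numeric(1), "test_potential_mV")
    stopifnot_msg(!anyDuplicated(vm),
                  "duplicate test potentials in an I-V protocol")
  }
  structure(list(sweeps = sweeps, protocol = protocol,
                 cell_capacitance_pF = cell_capacitance_pF),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> protocol %s: %d sweeps, Cm %.1f pF\n",
              x$protocol, length(x$sweeps), x$cell_capacitance_pF))
  invisible(x)
}

# indices of the pulse window, optionally after capacitive-transient blanking
pulse_indices <- function(sweep, blank_ms = 0) {
  which(sweep$time_ms >= sweep$pulse_start_ms + blank_ms &
          sweep$time_ms <= sweep$pulse_start_ms + sweep$pulse_duration_ms)
}

# mean current over the last `frac` of the pulse window
end_of_pulse_level <- function(sweep, frac = 0.05) {
  t1 <- sweep$pulse_start_ms + sweep$pulse_duration_ms
  t0 <- t1 - frac * sweep$pulse_duration_ms
  mean(sweep$current_pA[sweep$time_ms >= t0 & sweep$time_ms <= t1])
}

# mean current before the pulse
baseline_level <- function(sweep) {
  pre <- sweep$time_ms < sweep$pulse_start_ms
  if (!any(pre)) 0 else mean(sweep$current_pA[pre])
}

#' Read a voltage-clamp sweep bundle from a directory
#'
#' A bundle is a directory with a `protocol.json` file (fields: `protocol`,
#' `capacitance_pF`, `sampling_hz`, and a `sweeps` array giving, per sweep,
#' `file`, `test_potential_mV`, `holding_potential_mV`, `pulse_start_ms`,
#' `pulse_duration_ms`, and optionally `prepulse_mV`, `interval_ms`) plus
#' one two-column delimited trace file (time_ms, current_pA) per sweep.
#'
#' @param dir Bundle directory.
#' @return A [sweep_set()].
#' @export
read_sweep_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "protocol.json"),
                              simplifyVector = TRUE)
  sw <- lapply(seq_len(nrow(meta$sweeps)), function(i) {
    rec <- meta$sweeps[i, ]
    tr <- read.table(file.path(dir, rec$file), comment.char = "#",
                     col.names = c("time_ms", "current_pA"))
    clamp_sweep(tr$time_ms, tr$current_pA, rec$test_potential_mV,
                rec$holding_potential_mV, rec$pulse_start_ms,
                rec$pulse_duration_ms,
                prepulse_mV = if ("prepulse_mV" %in% names(rec))
                  rec$prepulse_mV else NA_real_,
                interval_ms = if ("interval_ms" %in% names(rec))
                  rec$interval_ms else NA_real_)
  })
  sweep_set(sw, meta$protocol, meta$capacitance_pF)
}

#' Write a sweep set as a bundle directory
#'
#' Inverse of [read_sweep_bundle()].
#'
#' @param set A [sweep_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_bundle <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(seq_along(set$sweeps), function(i) {
    s <- set$sweeps[[i]]
    f <- sprintf("sweep_%03d.tsv", i)
    write.table(data.frame(time_ms = s$time_ms, current_pA = s$current_pA),
                file.path(dir, f), sep = "\t", row.names = FALSE,
                col.names = FALSE)
    data.frame(file = f, test_potential_mV = s$test_potential_mV,
               holding_potential_mV = s$holding_potential_mV,
               pulse_start_ms = s$pulse_start_ms,
               pulse_duration_ms = s$pulse_duration_ms,
               prepulse_mV = s$prepulse_mV, interval_ms = s$interval_ms)
  })
  meta <- list(protocol = set$protocol,
               capacitance_pF = set$cell_capacitance_pF,
               sweeps = do.call(rbind, recs))
  jsonlite::write_json(meta, file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
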