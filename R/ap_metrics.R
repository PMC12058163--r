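#' Action-potential metrics
#'
#' From a current-clamp voltage trace holding a single evoked action
#' potential:
#' \itemize{
#'   \item RMP: mean voltage over the pre-stimulus window;
#'   \item APA: peak voltage minus RMP;
#'   \item APDx: time from the AP peak (or, optionally, the upstroke
#'     midpoint) until the voltage first falls below
#'     `peak - x\% * APA`, with linear interpolation between samples.
#' }
#' APD20 <= APD50 <= APD90 holds for any monotone repolarization.
#'
#' @param trace A [clamp_sweep()] whose `current_pA` slot carries membrane
#'   voltage (mV); `pulse_start_ms`/`pulse_duration_ms` describe the
#'   stimulus.
#' @param levels Repolarization percentages (default `c(20, 50, 90)`).
#' @param reference `"peak"` (default) or `"upstroke"` (the midpoint of the
#'   upstroke, where V crosses RMP + APA/2).
#' @param min_apa_mV Minimum amplitude for a trace to count as an AP
#'   (default 10 mV); smaller deflections raise an error.
#' @return An `ap_metrics` list: `RMP_mV`, `APA_mV`, `peak_mV`, and one
#'   `APDxx_ms` per level.
#' @examples
#' # idealized trapezoidal AP: linear 100-ms repolarization
#' t <- seq(0, 150, by = 0.05)
#' v <- ifelse(t < 10, -80,
#'   ifelse(t < 11, -80 + 120 * (t - 10),
#'     ifelse(t < 111, 40 - 120 * (t - 11) / 100, -80)))
#' ap <- clamp_sweep(t, v, NA, NA, 10, 2)
#' ap_metrics(ap)$APD90_ms # 90
#' @export
ap_metrics <- function(trace, levels = c(20, 50, 90),
                       reference = c("peak", "upstroke"), min_apa_mV = 10) {
  reference <- match.arg(reference)
  stopifnot_msg(inherits(trace, "clamp_sweep"), "trace must be a clamp_sweep")
  v <- trace$current_pA
  t <- trace$time_ms
  pre <- t < trace$pulse_start_ms
  stopifnot_msg(any(pre), "no pre-stimulus window for the RMP")
  rmp <- mean(v[pre])
  ip <- which.max(v)
  apa <- v[ip] - rmp
  stopifnot_msg(apa >= min_apa_mV,
                sprintf("no AP elicited (amplitude %.1f mV < %.0f mV)",
                        apa, min_apa_mV))
  t_ref <- if (reference == "peak") t[ip] else {
    on <- which(t >= trace$pulse_start_ms)[1]
    tc <- cross_time(t, v, rmp + apa / 2, from = on, dir = 1L, cmp = "above")
    if (is.na(tc)) t[ip] else tc
  }
  out <- list(RMP_mV = rmp, APA_mV = apa, peak_mV = v[ip])
  for (x in levels) {
    lvl <- v[ip] - x / 100 * apa
    tc <- cross_time(t, v, lvl, from = ip, dir = 1L, cmp = "below")
    out[[sprintf("APD%d_ms", x)]] <-
      if (is.na(tc)) NA_real_ else tc - t_ref
  }
  structure(out, class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat(sprintf("<ap_metrics> RMP %.1f mV  APA %.1f mV  %s\n", x$RMP_mV,
              x$APA_mV,
              paste(grep("^APD", names(x), value = TRUE),
                    sprintf("%.1f", unlist(x[grep("^APD", names(x))])),
                    sep = "=", collapse = "  ")))
  invisible(x)
}
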