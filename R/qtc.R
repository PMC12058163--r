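#' Heart-rate-corrected QT intervals
#'
#' Three QTc conventions used across human and murine ECG work:
#' \describe{
#'   \item{Bazett (human)}{`QTc = QT / sqrt(RR)` with RR in seconds. RR is
#'     derived from heart rate (`RR = 60/HR` s). Integer-millisecond
#'     reporting truncates toward zero.}
#'   \item{Hodges}{`QTc = QT + 1.75 * (HR - 60)`; integer reporting rounds
#'     half up.}
#'   \item{Murine normalization (Mitchell)}{`QTc = QT / sqrt(RR/100)` with
#'     RR in ms: the mouse analogue of Bazett normalized to RR = 100 ms.}
#' }
#' All three are identities at their reference rate (HR 60 bpm for the
#' human formulas, RR 100 ms for the murine one) and strictly increasing in
#' QT at fixed rate. Full precision is kept in `qtc_ms`; the reporting-mode
#' integer is in `qtc_int`.
#'
#' @param qt_ms QT interval (ms).
#' @param hr_bpm Heart rate (bpm), > 0.
#' @param rr_ms RR interval (ms), > 0 (murine formula).
#' @return A `qtc_value` list: `qt_ms`, `rr_ms`, `hr_bpm`, `formula`,
#'   `qtc_ms` (full precision), `qtc_int` (reporting-mode integer).
#' @examples
#' qtc_bazett_human(480, 65)$qtc_int # 499
#' qtc_hodges(400, 95)$qtc_int # 461
#' qtc_mitchell_mouse(60, 400)$qtc_ms # 30
#' @name qtc
NULL

qtc_value <- function(qt_ms, rr_ms, hr_bpm, formula, qtc_ms, qtc_int) {
  structure(list(qt_ms = qt_ms, rr_ms = rr_ms, hr_bpm = hr_bpm,
                 formula = formula, qtc_ms = qtc_ms, qtc_int = qtc_int),
            class = "qtc_value")
}

#' @export
print.qtc_value <- function(x, ...) {
  cat(sprintf("<qtc_value> %s: QT %.4g ms @ %.4g bpm -> QTc %.2f ms (%d)\n",
              x$formula, x$qt_ms, x$hr_bpm, x$qtc_ms, x$qtc_int))
  invisible(x)
}

# round half up to integer (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' @rdname qtc
#' @export
qtc_bazett_human <- function(qt_ms, hr_bpm) {
  stopifnot_msg(all(hr_bpm > 0), "hr_bpm must be > 0")
  rr_s <- 60 / hr_bpm
  qtc <- qt_ms / sqrt(rr_s)
  qtc_value(qt_ms, rr_s * 1000, hr_bpm, "bazett_human", qtc,
            as.integer(trunc(qtc)))
}

#' @rdname qtc
#' @export
qtc_hodges <- function(qt_ms, hr_bpm) {
  stopifnot_msg(all(hr_bpm > 0), "hr_bpm must be > 0")
  qtc <- qt_ms + 1.75 * (hr_bpm - 60)
  qtc_value(qt_ms, 60000 / hr_bpm, hr_bpm, "hodges", qtc,
            as.integer(round_half_up(qtc)))
}

#' @rdname qtc
#' @export
qtc_mitchell_mouse <- function(qt_ms, rr_ms) {
  stopifnot_msg(all(rr_ms > 0), "rr_ms must be > 0")
  qtc <- qt_ms / sqrt(rr_ms / 100)
  qtc_value(qt_ms, rr_ms, 60000 / rr_ms, "mitchell_mouse", qtc,
            as.integer(round_half_up(qtc)))
}
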