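#' Short-term QT variability markers
#'
#' The six beat-to-beat QT variability statistics used as arrhythmia-risk
#' markers, computed on an ordered QT series (ms) and, for the variability
#' index, an aligned heart-rate series (bpm):
#' \describe{
#'   \item{QTvar}{unbiased sample variance of the QT series (ms^2).}
#'   \item{SDqt}{`sqrt(QTvar)` (ms).}
#'   \item{STVqt}{short-term variability: the mean absolute successive
#'     difference divided by `sqrt(2)` (ms). The denominator counts the
#'     `n - 1` successive differences by default; a conventional fixed
#'     30-beat denominator is available via `denominator = "fixed30"`.}
#'   \item{QTVN}{QT variance normalized to the squared mean QT
#'     (dimensionless).}
#'   \item{QTVI}{`log10` of the ratio of normalized QT variance to
#'     normalized HR variance (dimensionless).}
#'   \item{RMSSDqt}{root mean square of successive differences:
#'     `sqrt(sum(diff^2) / (n - 1))` (ms).}
#' }
#'
#' @param qt_ms Numeric vector of beat-to-beat QT intervals (ms), length
#'   >= 2, all positive.
#' @param hr_bpm Numeric vector of beat-wise heart rates (bpm), same length
#'   as `qt_ms` (QTVI only).
#' @param qtm,hrm Optional externally supplied means; by default the means
#'   of the analyzed series themselves are used.
#' @param denominator `"diffs"` (default; divide by the number of
#'   successive differences) or `"fixed30"` (conventional 30-beat window).
#' @return The marker value; [qtv_panel()] returns all six as a one-row
#'   data.frame of class `qtv_panel`.
#' @examples
#' qt <- c(400, 410, 400, 420, 405)
#' sdqt(qt)^2 == qtvar(qt)
#' rmssdqt(c(400, 420)) # 20
#' @name qt_variability
NULL

check_qt_series <- function(qt_ms) {
  stopifnot_msg(is.numeric(qt_ms) && length(qt_ms) >= 2L,
                "QT series must contain at least 2 beats")
  stopifnot_msg(all(is.finite(qt_ms)) && all(qt_ms > 0),
                "QT series must be finite and positive")
}

#' @rdname qt_variability
#' @export
qtvar <- function(qt_ms) {
  check_qt_series(qt_ms)
  var(qt_ms)
}

#' @rdname qt_variability
#' @export
sdqt <- function(qt_ms) sqrt(qtvar(qt_ms))

#' @rdname qt_variability
#' @export
stvqt <- function(qt_ms, denominator = c("diffs", "fixed30")) {
  check_qt_series(qt_ms)
  denominator <- match.arg(denominator)
  d <- abs(diff(qt_ms))
  nd <- if (denominator == "fixed30") 30 else length(d)
  sum(d) / (nd * sqrt(2))
}

#' @rdname qt_variability
#' @export
qtvn <- function(qt_ms, qtm = mean(qt_ms)) {
  check_qt_series(qt_ms)
  qtvar(qt_ms) / qtm^2
}

#' @rdname qt_variability
#' @export
qtvi_hr <- function(qt_ms, hr_bpm, qtm = mean(qt_ms), hrm = mean(hr_bpm)) {
  check_qt_series(qt_ms)
  stopifnot_msg(length(hr_bpm) >= 2L && all(is.finite(hr_bpm)),
                "HR series must contain at least 2 finite values")
  hrv <- var(hr_bpm)
  stopifnot_msg(hrv > 0, "QTVI undefined: HR variance is zero")
  log10((qtvar(qt_ms) / qtm^2) / (hrv / hrm^2))
}

#' @rdname qt_variability
#' @export
rmssdqt <- function(qt_ms) {
  check_qt_series(qt_ms)
  d <- diff(qt_ms)
  sqrt(sum(d^2) / (length(qt_ms) - 1L))
}

#' @rdname qt_variability
#' @param na_qtvi If the HR variance is zero, report QTVI as `-Inf` with a
#'   flag instead of erroring (panel only; default TRUE).
#' @export
qtv_panel <- function(qt_ms, hr_bpm = NULL,
                      denominator = c("diffs", "fixed30"),
                      na_qtvi = TRUE) {
  check_qt_series(qt_ms)
  denominator <- match.arg(denominator)
  qv <- qtvar(qt_ms)
  qtvi <- NA_real_
  qtvi_flag <- NA_character_
  if (!is.null(hr_bpm)) {
    stopifnot_msg(length(hr_bpm) == length(qt_ms),
                  "HR series must align beat-wise with the QT series")
    if (qv == 0 || var(hr_bpm) == 0) {
      if (!na_qtvi) stop("QTVI undefined on degenerate series", call. = FALSE)
      qtvi <- if (qv == 0) -Inf else Inf
      qtvi_flag <- "degenerate"
    } else {
      qtvi <- qtvi_hr(qt_ms, hr_bpm)
    }
  }
  out <- data.frame(
    QTvar = qv, SDqt = sqrt(qv),
    STVqt = stvqt(qt_ms, denominator),
    QTVN = qtvn(qt_ms), QTVI = qtvi, RMSSDqt = rmssdqt(qt_ms)
  )
  attr(out, "qtvi_flag") <- qtvi_flag
  class(out) <- c("qtv_panel", class(out))
  out
}

#' Read a beat-to-beat QT (and optional HR) series from delimited text
#'
#' One column (`qt_ms`) or two (`qt_ms`, `hr_bpm`); `#` comment lines are
#' skipped.
#'
#' @param path File path.
#' @return A data.frame with `qt_ms` and, if present, `hr_bpm`.
#' @export
read_qt_series <- function(path) {
  dat <- read.table(path, comment.char = "#")
  names(dat) <- c("qt_ms", "hr_bpm")[seq_len(ncol(dat))]
  dat
}
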