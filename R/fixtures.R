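FIXTURE_FILES <- c(table1 = "table1_patient_ecg.csv",
                   table2 = "table2_qt_variability.csv")
FIXTURE_MD5 <- c(table1 = "1b5b230f2cefbaab58fc01e738ac648a",
                 table2 = "6cfdc6d3ce6b653b09cc4b36911249bb")

#' Load a packaged patient-cohort fixture
#'
#' Verbatim transcriptions of the published patient tables, shipped with
#' the package and integrity-checked by MD5 on load:
#' \describe{
#'   \item{table1}{Per-subject ECG parameters for 4 LVNC patients carrying
#'     MIB1 mutations and 4 healthy-relative controls: heart rate, QT,
#'     printed Bazett and Hodges QTc, RR, PR, QRS, cardiac axis.}
#'   \item{table2}{The six short-term QT-variability markers for the same
#'     8 subjects.}
#' }
#' Values are stored as printed, with no recomputation.
#'
#' @param name `"table1"` or `"table2"`.
#' @return A data.frame, one row per subject.
#' @examples
#' tab1 <- load_fixture("table1")
#' table(tab1$group)
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "cardioqt",
                      mustWork = TRUE)
  got <- unname(tools::md5sum(path))
  stopifnot_msg(identical(got, FIXTURE_MD5[[name]]),
                sprintf("fixture '%s' failed its checksum (%s)", name, got))
  read.csv(path, check.names = FALSE)
}

#' Recompute QTc columns for a cohort table
#'
#' Applies [qtc_bazett_human()] (RR derived from heart rate; integer
#' truncation) and [qtc_hodges()] (round half up) to the `qt_ms` and
#' `hr_bpm` columns of a cohort table such as the table1 fixture.
#'
#' @param cohort Data.frame with columns `qt_ms` and `hr_bpm`.
#' @return The input with integer columns `qtc_bazett_recomputed_ms` and
#'   `qtc_hodges_recomputed_ms` appended.
#' @export
recompute_qtc <- function(cohort) {
  stopifnot_msg(all(c("qt_ms", "hr_bpm") %in% names(cohort)),
                "cohort must have qt_ms and hr_bpm columns")
  cohort$qtc_bazett_recomputed_ms <- vapply(
    seq_len(nrow(cohort)),
    function(i) qtc_bazett_human(cohort$qt_ms[i], cohort$hr_bpm[i])$qtc_int,
    integer(1))
  cohort$qtc_hodges_recomputed_ms <- vapply(
    seq_len(nrow(cohort)),
    function(i) qtc_hodges(cohort$qt_ms[i], cohort$hr_bpm[i])$qtc_int,
    integer(1))
  cohort
}
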