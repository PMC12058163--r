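Package: cardioqt
Title: Cardiac Electrophysiology and Histology Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis toolkit for cardiac electrophysiology
    studies of left ventricular non-compaction (LVNC) and related
    cardiomyopathies. Delineates single-lead ECGs into per-beat fiducials
    and averaged PR/QRS/QT/RR intervals, applies heart-rate corrections to
    the QT interval (Bazett, Hodges, and the murine square-root-of-RR/100
    normalization), and computes the short-term QT-variability panel
    (QTvar, SDqt, STVqt, QTVN, QTVI, RMSSDqt). Analyzes whole-cell
    voltage-clamp sweep sets: current-voltage relationships, Boltzmann
    gating fits, exponential activation/inactivation kinetics, recovery
    from inactivation, late-current fractions, charge integration, and
    action-potential duration metrics. Quantifies connexin-43
    co-localization with intercalated disks, lateralization ratios, and
    picrosirius-red fibrosis fractions on co-registered binary masks.
    Every input class has a synthetic generator with machine-readable
    ground truth so the full pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
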