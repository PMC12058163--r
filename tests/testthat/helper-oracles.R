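# Independent brute-force implementations of the QT-variability markers,
# written as explicit loops so they share no code path with the package.

oracle_qtvar <- function(qt) {
  n <- length(qt)
  m <- 0
  for (x in qt) m <- m + x / n
  s <- 0
  for (x in qt) s <- s + (x - m)^2
  s / (n - 1)
}

oracle_sdqt <- function(qt) sqrt(oracle_qtvar(qt))

oracle_stvqt <- function(qt) {
  s <- 0
  nd <- 0
  for (i in seq_len(length(qt) - 1)) {
    s <- s + abs(qt[i + 1] - qt[i])
    nd <- nd + 1
  }
  s / (nd * sqrt(2))
}

oracle_qtvn <- function(qt) {
  m <- 0
  for (x in qt) m <- m + x / length(qt)
  oracle_qtvar(qt) / m^2
}

oracle_qtvi <- function(qt, hr) {
  mh <- 0
  for (x in hr) mh <- mh + x / length(hr)
  log10(oracle_qtvn(qt) / (oracle_qtvar(hr) / mh^2))
}

oracle_rmssdqt <- function(qt) {
  s <- 0
  for (i in seq_len(length(qt) - 1)) s <- s + (qt[i + 1] - qt[i])^2
  sqrt(s / (length(qt) - 1))
}

# a simple binary dilation by one pixel (4-neighbourhood), used for the
# fibrosis monotonicity property
dilate1 <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  storage.mode(out) <- "integer"
  out
}
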