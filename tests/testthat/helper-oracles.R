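# Independent brute-force oracles, coded separately from the package
# internals on purpose: each one evaluates the defining formula directly,
# element by element, with no shared helpers.

oracle_backproject <- function(fx, fy, cx, cy, x, y, D) {
  out <- matrix(NA_real_, length(x), 3)
  for (i in seq_along(x)) {
    out[i, 1] <- D[i] * (cx - x[i]) / fx
    out[i, 2] <- D[i] * (cy - y[i]) / fy
    out[i, 3] <- D[i]
  }
  out
}

oracle_pair_distance <- function(fx, fy, cx, cy, p1, p2, d1, d2) {
  Dbar <- (d1 + d2) / 2
  a <- c(Dbar * (cx - p1[1]) / fx, Dbar * (cy - p1[2]) / fy, Dbar)
  b <- c(Dbar * (cx - p2[1]) / fx, Dbar * (cy - p2[2]) / fy, Dbar)
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
}

oracle_rmse <- function(d, phi) {
  acc <- 0
  for (v in d) acc <- acc + (v - phi)^2
  sqrt(acc / length(d))
}

oracle_mrae <- function(d, phi) {
  acc <- 0
  for (v in d) acc <- acc + sqrt((v - phi)^2) / phi
  acc / length(d)
}

oracle_fill_rate <- function(depthimg, roi) {
  vals <- c()
  for (i in seq_len(nrow(depthimg))) for (j in seq_len(ncol(depthimg)))
    if (roi[i, j] && depthimg[i, j] > 0) vals <- c(vals, depthimg[i, j])
  n_valid <- 0
  for (i in seq_len(nrow(depthimg))) for (j in seq_len(ncol(depthimg))) {
    if (!roi[i, j]) next
    v <- depthimg[i, j]
    if (v <= 0) next
    if (length(vals) < 2 || sd(vals) == 0 ||
        abs(v - mean(vals)) <= 3 * sd(vals)) n_valid <- n_valid + 1
  }
  n_valid / sum(roi)
}

oracle_filter_lines <- function(lengths) {
  if (length(lengths) < 2) return(seq_along(lengths))
  m <- mean(lengths); s <- sd(lengths)
  if (s == 0) return(seq_along(lengths))
  keep <- c()
  for (i in seq_along(lengths))
    if (abs(lengths[i] - m) <= 3 * s) keep <- c(keep, i)
  keep
}
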