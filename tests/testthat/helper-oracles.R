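# Independent brute-force oracles. Deliberately written as plain loops over
# definitions, never sharing code with the implementation they check.

# elementwise consecutive-frame difference
oracle_delta <- function(frames) {
  d <- dim(frames)
  out <- array(NA_real_, c(d[1], d[2], d[3] - 1L))
  for (t in seq_len(d[3] - 1L))
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        out[i, j, t] <- frames[i, j, t] - frames[i, j, t + 1L]
  out
}

# mean of absolute values, one scalar per difference frame
oracle_mean_abs <- function(deltas) {
  d <- dim(deltas)
  out <- numeric(d[3])
  for (t in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        s <- s + abs(deltas[i, j, t])
    out[t] <- s / (d[1] * d[2])
  }
  out
}

# block means with ragged edges
oracle_block_mean <- function(mat, b) {
  nr <- ceiling(nrow(mat) / b); nc <- ceiling(ncol(mat) / b)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      rows <- ((i - 1L) * b + 1L):min(i * b, nrow(mat))
      cols <- ((j - 1L) * b + 1L):min(j * b, ncol(mat))
      out[i, j] <- mean(mat[rows, cols])
    }
  out
}

# exhaustive Otsu on integer-valued pools: tries every candidate threshold
# (foreground = value < t), maximizing between-class variance; smallest
# maximizer wins
oracle_otsu_int <- function(v) {
  cands <- (min(v) + 1L):max(v)
  best_t <- NA_real_; best_bcv <- -Inf
  for (t in cands) {
    fg <- v < t
    w0 <- mean(fg)
    if (w0 == 0 || w0 == 1) next
    bcv <- w0 * (1 - w0) * (mean(v[fg]) - mean(v[!fg]))^2
    if (bcv > best_bcv + 1e-9 * max(best_bcv, 1)) {
      best_bcv <- bcv; best_t <- t
    }
  }
  best_t
}

# interaction-loss transition count of one boolean pixel history
oracle_transitions <- function(x) {
  n <- 0L
  for (t in seq_len(length(x) - 1L))
    if (x[t] && !x[t + 1L]) n <- n + 1L
  n
}

# two-pass mean / population sd
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  s2 <- 0
  for (v in x) s2 <- s2 + (v - m)^2
  c(mean = m, sd = sqrt(s2 / length(x)))
}
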