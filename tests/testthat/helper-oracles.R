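# Independent brute-force oracles. These re-derive every selection rule with
# plain loops (strict comparisons keep leftmost ties) and are deliberately
# written without reusing package internals.

# Moving average with clamped (replicated) indices; window must be odd.
bf_smooth <- function(y, window) {
  if (window <= 1L) return(y)
  n <- length(y)
  r <- (window - 1L) %/% 2L
  s <- numeric(n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax((i - r):(i + r), 1L), n)
    s[i] <- mean(y[idx])
  }
  s
}

bf_cdiff <- function(y) {
  n <- length(y)
  g <- rep(NA_real_, n)
  for (i in 2:(n - 1)) g[i] <- (y[i + 1] - y[i - 1]) / 2
  g
}

# Exhaustive scan over all adjacent-difference pairs: steepest decline, then
# steepest incline strictly to its right. Returns NA components when no
# qualifying column exists.
bf_borders <- function(y, window = 1L) {
  g <- bf_cdiff(bf_smooth(y, window))
  n <- length(g)
  med <- NA_integer_
  for (i in 2:(n - 1)) {
    if (!is.na(g[i]) && g[i] < 0 && (is.na(med) || g[i] < g[med])) med <- i
  }
  if (is.na(med)) return(list(medial = NA_integer_, lateral = NA_integer_))
  lat <- NA_integer_
  if (med + 1L <= n - 1L) {
    for (j in (med + 1L):(n - 1L)) {
      if (!is.na(g[j]) && g[j] > 0 && (is.na(lat) || g[j] > g[lat])) lat <- j
    }
  }
  list(medial = med, lateral = lat)
}

# Leftmost argmax by exhaustive scan.
bf_argmax <- function(y) {
  best <- 1L
  for (i in seq_along(y)) if (y[i] > y[best]) best <- i
  best
}

# Derivative argmax inside the crop window ending at the peak.
bf_inflection <- function(y, peak, crop_cols) {
  g <- bf_cdiff(y)
  w0 <- max(2L, peak - crop_cols)
  best <- NA_integer_
  for (i in (w0 + 1L):(peak - 1L)) {
    if (is.na(best) || g[i] > g[best]) best <- i
  }
  best
}

# Sort-based median and definition-based sample SD.
bf_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

bf_sd <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

# Shared small fixtures -------------------------------------------------

step_profile <- function(drop_at = 40L, rise_at = 200L, n = 256L,
                         high = 1, low = 0.2, spacing = 0.5) {
  y <- rep(high, n)
  y[(drop_at + 1L):rise_at] <- low
  new("RowProfile", intensities = y, rowIndex = 1L, colSpacingMm = spacing)
}

quiet_phantom <- function(...) phantomSpec(noiseSigma = 0, ...)
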