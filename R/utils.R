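#' @importFrom rlang %||% .data abort warn
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of first last
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map2 pmap imap map_dfr
#' @importFrom stats sd median qt pt quantile var aov TukeyHSD cor
#'   pf rnorm runif setNames approx spline complete.cases
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Trapezoidal integral of y over x (seconds).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Zero-phase Butterworth low-pass. `order` is the per-pass order; filtfilt
# doubles the effective order. Odd-reflection padding suppresses start/end
# transients. Returns x unchanged when cutoff_hz is NULL/0.
lowpass_zero_phase <- function(x, rate, cutoff_hz, order = 2L) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || !is.finite(cutoff_hz)) return(x)
  if (cutoff_hz >= rate / 2) return(x)
  butter_zero_phase(x, rate, cutoff_hz, order, "low")
}

# Linear-phase FIR low-pass (Hamming-windowed sinc), centred so it is
# exactly zero phase; DC gain normalised to 1 so constants and linear
# trends pass unchanged. Used for CoM differentiation where passband
# flatness matters more than rolloff steepness.
fir_lowpass_zero_phase <- function(x, rate, cutoff_hz, trans_hz = 1) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || !is.finite(cutoff_hz)) return(x)
  if (cutoff_hz >= rate / 2) return(x)
  n <- length(x)
  half <- min((n - 1L), ceiling(3.3 * rate / trans_hz / 2))
  k <- seq(-half, half)
  fc <- (cutoff_hz + trans_hz / 2) / rate       # edge of transition band
  h <- 2 * fc * sinc_fun(2 * fc * k) *
    (0.54 + 0.46 * cos(pi * k / half))          # Hamming window
  h <- h / sum(h)
  head_pad <- 2 * x[1] - x[(half + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - half)]
  y <- stats::convolve(c(head_pad, x, tail_pad), rev(h), type = "filter")
  as.numeric(y)
}

sinc_fun <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# padded forward-backward Butterworth of either type
butter_zero_phase <- function(x, rate, cutoff_hz, order, type) {
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = type)
  n <- length(x)
  p <- min(n - 1L, max(50L, ceiling(3 * rate / cutoff_hz)))
  head_pad <- 2 * x[1] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(p + 1L):(p + n)]
}

# Local maxima indices of x with a minimum index separation; among candidates
# closer than min_sep the larger value wins (ties -> earliest frame).
find_peaks <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # flat-top plateaus: take the first frame of the plateau
  cand <- which(d[-1] <= 0 & d[-(n - 1L)] > 0) + 1L
  plateau <- which(d[-1] < 0 & d[-(n - 1L)] == 0) + 1L
  if (length(plateau)) {
    for (p in plateau) {
      q <- p
      while (q > 1L && x[q - 1L] == x[p]) q <- q - 1L
      if (q > 1L && x[q - 1L] < x[p]) cand <- c(cand, q)
    }
    cand <- sort(unique(cand))
  }
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  keep <- logical(0)
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_sep)) sel <- c(sel, i)
  }
  sort(sel)
}

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")

assert_that <- function(cond, msg) if (!isTRUE(cond)) rlang::abort(msg)
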