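# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Colored (1/f^slope) Gaussian noise
#'
#' Generates zero-mean Gaussian noise whose power spectrum falls off as
#' `1/f^slope`, by shaping the Fourier amplitudes of random phases. The output
#' is scaled to unit standard deviation.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param slope spectral exponent of the power spectrum (0 = white, 1 = pink).
#' @return numeric vector of length `n`, sd 1.
#' @keywords internal
one_over_f_noise <- function(n, fs, slope = 1) {
  stopifnot(n > 3, fs > 0, slope >= 0)
  # pad to a power of two: R's mixed-radix FFT degrades badly on other lengths
  np <- stats::nextn(n, 2L)
  nf <- np %/% 2L
  f <- seq_len(nf) * fs / np
  amp <- f^(-slope / 2)
  full <- complex(length.out = np)
  full[2:(nf + 1L)] <- complex(modulus = amp, argument = runif(nf, 0, 2 * pi))
  # Hermitian symmetry so the inverse transform is real
  full[np:(np - nf + 2L)] <- Conj(full[2:nf])
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

#' Weighted quantile with linear interpolation
#'
#' Generalizes the type-7 sample quantile to weighted observations: plotting
#' positions are `(cumw_i - w_i) / (W - w_n)` on the sorted values, which
#' reduces to `(i - 1) / (n - 1)` (type 7) under equal weights.
#'
#' @param x numeric values.
#' @param w positive weights, recycled if length 1.
#' @param probs quantile levels in `[0, 1]`.
#' @return numeric vector of quantiles.
#' @keywords internal
weighted_quantile <- function(x, w = 1, probs = 0.5) {
  stopifnot(length(x) > 0, all(is.finite(x)), all(w > 0), all(probs >= 0 & probs <= 1))
  w <- rep_len(w, length(x))
  o <- order(x)
  x <- x[o]; w <- w[o]
  if (length(x) == 1L) return(rep(x, length(probs)))
  cw <- cumsum(w)
  pos <- (cw - w) / (cw[length(cw)] - w[length(w)])
  vapply(probs, function(p) stats::approx(pos, x, xout = p, rule = 2, ties = "ordered")$y,
         numeric(1))
}

# Hamming window of length n (periodic-symmetric convention used for tapers).
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Cache for filter designs, keyed by parameter string.
.filter_cache <- new.env(parent = emptyenv())

cached_filter <- function(key, design_fun) {
  if (is.null(.filter_cache[[key]])) .filter_cache[[key]] <- design_fun()
  .filter_cache[[key]]
}

# Connected components among `nodes` (integer channel indices) of an adjacency
# neighbor list. Returns a list of integer vectors. Small hand-rolled BFS:
# this runs inside permutation loops, so per-call overhead matters.
connected_components <- function(nodes, neighbors) {
  if (length(nodes) == 0L) return(list())
  in_set <- logical(length(neighbors))
  in_set[nodes] <- TRUE
  seen <- logical(length(neighbors))
  comps <- vector("list", length(nodes))
  nc <- 0L
  for (v in nodes) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      members <- c(members, u)
      nb <- neighbors[[u]]
      nb <- nb[in_set[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    nc <- nc + 1L
    comps[[nc]] <- sort(members)
  }
  comps[seq_len(nc)]
}

stop_localwake <- function(msg, class) {
  stop(structure(class = c(class, "localwake_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
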