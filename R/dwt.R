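# Periodized orthogonal discrete wavelet transform (pyramid algorithm).
# Daubechies filters; circular convolution keeps the transform orthonormal,
# so synthesis is the exact adjoint of analysis.

.db4_h <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

.wt_filters <- function(wavelet = "db4") {
  h <- switch(wavelet,
              db4 = .db4_h,
              haar = c(1, 1) / sqrt(2),
              stop("unknown wavelet: ", wavelet))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, L = L)
}

# One analysis level: x (even length) -> list(a, d) of length n/2.
.dwt_step <- function(x, flt) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_len(flt$L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + flt$h[m] * x[idx]
    d <- d + flt$g[m] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis level (adjoint of .dwt_step).
.idwt_step <- function(a, d, flt) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_len(flt$L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + flt$h[m] * a + flt$g[m] * d
  }
  x
}

#' Multi-level discrete wavelet decomposition
#'
#' Periodized orthonormal DWT. The input length must be divisible by
#' \code{2^levels}.
#'
#' @param x numeric signal.
#' @param levels decomposition depth.
#' @param wavelet \code{"db4"} (default) or \code{"haar"}.
#' @return List with \code{approx} (coarsest approximation) and
#'   \code{details} (list, finest level first).
#' @keywords internal
dwt_decompose <- function(x, levels, wavelet = "db4") {
  flt <- .wt_filters(wavelet)
  if (length(x) %% 2^levels != 0)
    stop("signal length must be divisible by 2^levels")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- .dwt_step(a, flt)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, wavelet = wavelet)
}

#' @rdname dwt_decompose
#' @param dec a decomposition as returned by \code{dwt_decompose}.
#' @keywords internal
dwt_reconstruct <- function(dec) {
  flt <- .wt_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_along(dec$details)))
    a <- .idwt_step(a, dec$details[[j]], flt)
  a
}
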