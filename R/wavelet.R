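# Daubechies order-2 analysis filters (4 taps).
DB2_LO <- c(
  -0.12940952255126037, 0.22414386804201340,
  0.83651630373780790, 0.48296291314453416
)
DB2_HI <- c(
  -0.48296291314453416, 0.83651630373780790,
  -0.22414386804201340, -0.12940952255126037
)

# One analysis step of the dyadic filter bank as a pair of matrices, cached
# per input length. The signal is extended by half-sample symmetry
# (edge sample repeated), convolved with the analysis filters, and
# downsampled by two; output length floor((n + 3) / 2). This reproduces the
# standard symmetric-extension DWT used by mainstream wavelet toolboxes.
.dwt_cache <- new.env(parent = emptyenv())

dwt_operator <- function(n) {
  key <- as.character(n)
  if (!is.null(.dwt_cache[[key]])) return(.dwt_cache[[key]])
  fl <- length(DB2_LO) # 4
  if (n < fl - 1) {
    stop("signal of length ", n, " too short for one db2 analysis step",
      call. = FALSE
    )
  }
  n_out <- (n + fl - 1) %/% 2
  take <- fl + 1 + 2 * (seq_len(n_out) - 1) # indices into the full convolution
  ident <- diag(n)
  ext <- rbind(
    ident[(fl - 1):1, , drop = FALSE],
    ident,
    ident[n:(n - fl + 2), , drop = FALSE]
  )
  conv_rows <- function(filt) {
    m <- nrow(ext)
    out <- matrix(0, n_out, n)
    for (k in seq_len(n_out)) {
      # full-convolution row `take[k]`: sum_j filt[j] * ext[take[k] - j + 1]
      idx <- take[k] - seq_len(fl) + 1
      ok <- idx >= 1 & idx <= m
      out[k, ] <- colSums(filt[ok] * ext[idx[ok], , drop = FALSE])
    }
    out
  }
  op <- list(lo = conv_rows(DB2_LO), hi = conv_rows(DB2_HI))
  .dwt_cache[[key]] <- op
  op
}

#' Frequency bands of a dyadic wavelet decomposition
#'
#' Detail level `l` covers `(fs/2^(l+1), fs/2^l)` Hz and the final
#' approximation covers `(0, fs/2^(levels+1))`. At `fs = 256` with five levels
#' this is the canonical brainwave mapping: D1 64-128 (high gamma),
#' D2 32-64 (gamma), D3 16-32 (beta), D4 8-16 (alpha), D5 4-8 (theta),
#' A5 0-4 (delta).
#'
#' @param fs sampling rate in Hz.
#' @param levels decomposition depth.
#' @return named list of `c(low, high)` pairs, `D1..D<levels>` then
#'   `A<levels>`.
#' @export
#' @examples
#' wavelet_band_edges(256, 5)$D1
wavelet_band_edges <- function(fs, levels = 5L) {
  out <- lapply(seq_len(levels), function(l) c(fs / 2^(l + 1), fs / 2^l))
  names(out) <- paste0("D", seq_len(levels))
  out[[paste0("A", levels)]] <- c(0, fs / 2^(levels + 1))
  out
}

# Batch decomposition: X is window_samples x m; returns a named list of
# coefficient matrices (one per band, coefficients x m). Shared by
# wavelet_decompose() and the feature builder, where m is
# segments * channels.
dwt_bands_matrix <- function(X, levels = 5L) {
  out <- vector("list", levels + 1L)
  names(out) <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  a <- X
  for (l in seq_len(levels)) {
    if (nrow(a) < length(DB2_LO) - 1) {
      stop("window too short to decompose at level ", l, call. = FALSE)
    }
    op <- dwt_operator(nrow(a))
    out[[paste0("D", l)]] <- op$hi %*% a
    a <- op$lo %*% a
  }
  out[[paste0("A", levels)]] <- a
  out
}

#' Five-level Daubechies-2 wavelet decomposition of one window
#'
#' Runs the dyadic analysis filter bank with symmetric (half-sample)
#' boundary extension and returns the detail coefficient vectors `D1..D5`
#' and the approximation `A5`, together with their frequency edges.
#'
#' @param window numeric vector, length >= 8.
#' @param wavelet wavelet name; only `"db2"` is implemented.
#' @param levels decomposition depth.
#' @param fs sampling rate in Hz (used only to label band edges).
#' @return list with `coefficients` (named list of numeric vectors) and
#'   `band_edges` (as [wavelet_band_edges()]).
#' @export
#' @examples
#' wb <- wavelet_decompose(sin(2 * pi * 100 * (0:60) / 256), fs = 256)
#' lengths(wb$coefficients)
wavelet_decompose <- function(window, wavelet = "db2", levels = 5L, fs = 256) {
  if (!identical(wavelet, "db2")) {
    stop("only the order-2 Daubechies wavelet is implemented", call. = FALSE)
  }
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  if (length(window) < 8) stop("window must have >= 8 samples", call. = FALSE)
  bands <- dwt_bands_matrix(matrix(window, ncol = 1), levels = levels)
  list(
    coefficients = lapply(bands, as.numeric),
    band_edges = wavelet_band_edges(fs, levels)
  )
}
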