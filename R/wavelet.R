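#' Concatenate both polarities of a FAIMS scan into one feature vector
#'
#' Row-major by dispersion-field line: the positive matrix's DF line 1
#' (512 CV values) comes first, then its remaining 50 lines, then the
#' negative matrix in the same order, giving 2 x 51 x 512 = 52,224 elements.
#'
#' @param scan a [faims_scan()].
#' @return numeric vector of length 52,224 with attribute `sample_id`.
#' @export
concatenate_polarities <- function(scan) {
  stopifnot(inherits(scan, "faims_scan"))
  v <- c(as.vector(t(scan$positive)), as.vector(t(scan$negative)))
  attr(v, "sample_id") <- scan$sample_id
  v
}

#' Map a feature-vector index back to (polarity, DF line, CV step)
#'
#' Inverse of the concatenation order; indices are 1-based.
#'
#' @param index integer vector of positions in `[1, 52224]`.
#' @return data frame with columns `polarity`, `df_line`, `cv_step`.
#' @export
faims_index_map <- function(index) {
  index <- as.integer(index)
  if (any(index < 1L | index > FAIMS_VECTOR_LENGTH)) {
    stop_format("index out of range [1, %d]", FAIMS_VECTOR_LENGTH)
  }
  i0 <- index - 1L
  pol <- ifelse(i0 < FAIMS_POINTS_PER_POLARITY, "positive", "negative")
  r <- i0 %% FAIMS_POINTS_PER_POLARITY
  data.frame(polarity = pol,
             df_line = r %/% FAIMS_N_CV + 1L,
             cv_step = r %% FAIMS_N_CV + 1L)
}

# Daubechies-4 analysis filters (2 vanishing moments, length 4),
# orthonormal: h = scaling, g = wavelet (quadrature mirror)
d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  list(h = h, g = c(h[4], -h[3], h[2], -h[1]))
}

dwt_step <- function(x) {
  n <- length(x)
  f <- d4_filters()
  xx <- c(x, x[1:2]) # periodic wrap for the last two taps
  e <- seq(1L, n, by = 2L)
  list(
    approx = f$h[1] * xx[e] + f$h[2] * xx[e + 1L] +
             f$h[3] * xx[e + 2L] + f$h[4] * xx[e + 3L],
    detail = f$g[1] * xx[e] + f$g[2] * xx[e + 1L] +
             f$g[3] * xx[e + 2L] + f$g[4] * xx[e + 3L]
  )
}

idwt_step <- function(approx, detail) {
  n <- 2L * length(approx)
  f <- d4_filters()
  y <- numeric(n)
  e <- seq(1L, n, by = 2L)
  for (j in 0:3) {
    pos <- (e - 1L + j) %% n + 1L
    y[pos] <- y[pos] + approx * f$h[j + 1L] + detail * f$g[j + 1L]
  }
  y
}

#' Multilevel Daubechies-4 wavelet transform
#'
#' Orthonormal periodic (circular) D4 decomposition of a 1-D signal. The
#' coefficient vector has the same length as the input and stores
#' `[approximation at depth L | detail L | detail L-1 | ... | detail 1]`.
#' Orthonormality means energy is conserved (Parseval) and
#' [inverse_wavelet()] reconstructs the input to numerical precision.
#'
#' The 52,224-element concatenated FAIMS vector halves evenly nine times
#' (down to 102 approximation coefficients), hence the default depth 9.
#'
#' @param v numeric vector; its length must be divisible by `2^levels`.
#' @param levels decomposition depth (>= 1).
#' @return object of class `wavelet_features`: `coefficients`, `levels`,
#'   `lengths` (per-block lengths), `sample_id`.
#' @export
wavelet_transform <- function(v, levels = 9L) {
  x <- as.numeric(v)
  n <- length(x)
  if (levels < 1L) stop_format("levels must be >= 1")
  if (n %% (2^levels) != 0L) {
    stop_format(paste("length %d is not divisible by 2^%d;",
                      "reduce the decomposition depth"), n, levels)
  }
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- dwt_step(x)
    details[[l]] <- st$detail
    x <- st$approx
  }
  structure(
    list(coefficients = c(x, unlist(details[rev(seq_len(levels))])),
         levels = as.integer(levels),
         lengths = c(length(x), lengths(details)[rev(seq_len(levels))]),
         sample_id = attr(v, "sample_id")),
    class = "wavelet_features"
  )
}

#' Invert a multilevel D4 wavelet transform
#'
#' @param w a `wavelet_features` object from [wavelet_transform()].
#' @return the reconstructed numeric vector.
#' @export
inverse_wavelet <- function(w) {
  stopifnot(inherits(w, "wavelet_features"))
  co <- w$coefficients
  lens <- w$lengths
  approx <- co[seq_len(lens[1])]
  offset <- lens[1]
  for (b in seq_along(lens)[-1]) {
    detail <- co[offset + seq_len(lens[b])]
    offset <- offset + lens[b]
    approx <- idwt_step(approx, detail)
  }
  out <- approx
  attr(out, "sample_id") <- w$sample_id
  out
}

#' @export
print.wavelet_features <- function(x, ...) {
  cat(sprintf("<wavelet_features> %d coefficients, depth %d\n",
              length(x$coefficients), x$levels))
  invisible(x)
}

#' Build the FAIMS wavelet feature matrix for a set of scans
#'
#' One row per sample: `wavelet_transform(concatenate_polarities(scan))`.
#' No per-sample normalization is applied by default (none is part of the
#' workflow); `normalize = "tic"` divides each concatenated vector by its
#' total ion current first.
#'
#' @param scans list of [faims_scan()] objects.
#' @param levels wavelet depth.
#' @param normalize `"none"` (default) or `"tic"`.
#' @return numeric matrix, samples x 52,224, rownames = sample ids.
#' @export
faims_feature_matrix <- function(scans, levels = 9L,
                                 normalize = c("none", "tic")) {
  normalize <- match.arg(normalize)
  rows <- vapply(scans, function(s) {
    v <- concatenate_polarities(s)
    if (normalize == "tic") v <- v / sum(v)
    wavelet_transform(v, levels = levels)$coefficients
  }, numeric(FAIMS_VECTOR_LENGTH))
  m <- t(rows)
  rownames(m) <- vapply(scans, function(s) s$sample_id, character(1))
  m
}
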