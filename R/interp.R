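# Spherical-spline scalp interpolation (Perrin et al. style): bad channels
# are reconstructed from the remaining channels via splines on the unit
# sphere. Stiffness m = 4 with 50 Legendre terms; the kernel series
# converges like n^(1-2m) so the truncation error is negligible.

legendre_poly <- function(x, n_max) {
  # rows: order 1..n_max, columns: values of x
  out <- matrix(0, nrow = n_max, ncol = length(x))
  p_prev <- rep(1, length(x))  # P0
  p <- x                       # P1
  out[1, ] <- p
  if (n_max > 1) {
    for (n in 2:n_max) {
      p_new <- ((2 * n - 1) * x * p - (n - 1) * p_prev) / n
      out[n, ] <- p_new
      p_prev <- p
      p <- p_new
    }
  }
  out
}

spline_g <- function(x, m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendre_poly(x, n_terms)
  as.numeric(crossprod(P, coef)) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Reconstructs the listed channels from the remaining ones by fitting a
#' spherical spline (stiffness 4) through the good-channel values and
#' evaluating it at the bad-channel positions. Constant scalp maps are
#' reproduced exactly.
#'
#' @param values Numeric matrix, samples x channels (or a vector for a
#'   single time point).
#' @param channels Channel labels for the columns of `values`.
#' @param bad Labels of channels to reconstruct.
#' @param positions data.frame from [montage_positions()] covering all
#'   channels.
#' @param lambda Ridge regularization added to the spline system diagonal.
#' @return `values` with the bad columns replaced.
#' @export
spherical_interpolate <- function(values, channels, bad,
                                  positions = montage_positions(channels),
                                  lambda = 1e-8) {
  vec_in <- is.null(dim(values))
  if (vec_in) values <- matrix(values, nrow = 1)
  if (length(bad) == 0) return(if (vec_in) values[1, ] else values)
  stopifnot(ncol(values) == length(channels), all(bad %in% channels))
  good <- setdiff(channels, bad)
  if (length(good) < 3) stop("need at least 3 good channels")
  pos <- positions[match(channels, positions$channel), c("x", "y", "z")]
  pos <- as.matrix(pos) / sqrt(rowSums(as.matrix(pos)^2))
  ig <- match(good, channels)
  ib <- match(bad, channels)

  cosang <- function(a, b) pmin(1, pmax(-1, tcrossprod(a, b)))
  G <- matrix(spline_g(as.numeric(cosang(pos[ig, , drop = FALSE],
                                         pos[ig, , drop = FALSE]))),
              nrow = length(ig))
  Gb <- matrix(spline_g(as.numeric(cosang(pos[ib, , drop = FALSE],
                                          pos[ig, , drop = FALSE]))),
               nrow = length(ib))
  k <- length(ig)
  A <- rbind(cbind(G + diag(lambda, k), rep(1, k)),
             c(rep(1, k), 0))
  rhs <- rbind(t(values[, ig, drop = FALSE]), 0)
  sol <- solve(A, rhs)
  c_coef <- sol[seq_len(k), , drop = FALSE]
  c0 <- sol[k + 1, ]
  est <- Gb %*% c_coef + matrix(c0, nrow = length(ib), ncol = ncol(sol),
                                byrow = TRUE)
  values[, ib] <- t(est)
  if (vec_in) values[1, ] else values
}

#' Detect and interpolate noisy channels in a continuous recording
#'
#' Channels are flagged when the robust z-score of their log variance
#' (median/MAD across channels) exceeds `z_thresh`, and replaced by
#' spherical-spline interpolation from the remaining channels.
#'
#' @param rec An [eeg_recording()].
#' @param positions Electrode positions covering all channels.
#' @param z_thresh Robust z threshold (default 3).
#' @return List with `rec` (channels repaired) and `bad_channels`.
#' @export
detect_and_interpolate_bads <- function(rec,
                                        positions =
                                          montage_positions(rec$channels),
                                        z_thresh = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  lv <- log(apply(rec$data, 2, stats::var) + 1e-12)
  med <- stats::median(lv)
  madv <- stats::mad(lv)
  z <- if (madv == 0) rep(0, length(lv)) else (lv - med) / madv
  bad <- rec$channels[abs(z) > z_thresh]
  if (length(bad) > 0.25 * length(rec$channels))
    stop(sprintf("more than 25%% of channels flagged bad (%d of %d)",
                 length(bad), length(rec$channels)))
  if (length(bad) > 0)
    rec$data <- spherical_interpolate(rec$data, rec$channels, bad, positions)
  list(rec = rec, bad_channels = bad)
}
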