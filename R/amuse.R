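#' AMUSE second-order blind source separation
#'
#' Algorithm for Multiple Unknown Signals Extraction: the data are whitened
#' by eigendecomposition of the zero-lag covariance, then the symmetrized
#' lag-`lag` covariance of the whitened data is eigendecomposed; its
#' eigenvectors give the unmixing rotation.  Components are mutually
#' uncorrelated at lag zero (unit variance) and are ordered by decreasing
#' lagged-covariance eigenvalue, i.e. from smoothest to least smooth.
#'
#' Rank deficiency introduced by linear constraints such as common-average
#' referencing is handled by discarding whitening eigenvalues below
#' `rank_tol` times the largest, so the decomposition operates in the
#' retained subspace; reconstruction without removing any component then
#' reproduces the input exactly (the discarded directions carry no data
#' variance).  Channels with (near) zero variance are an error: they make
#' the zero-lag covariance degenerate in a way no subspace choice can fix.
#'
#' @param rec an [eeg_recording] or channels x samples matrix.
#' @param lag covariance lag in samples (default 1, the canonical choice;
#'   larger lags sharpen separation of slow components at high sampling
#'   rates).
#' @param rank_tol relative eigenvalue cut-off for the retained subspace.
#' @return object of class `amuse_decomposition`: list with `components`
#'   (k x samples, unit variance), `mixing` (channels x k), `unmixing`
#'   (k x channels), `eigenvalues` (lagged-covariance eigenvalues),
#'   `center` (channel means removed before decomposition), `channels`.
#' @export
amuse_decompose <- function(rec, lag = 1L, rank_tol = 1e-10) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else rec
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  n <- nrow(x); tt <- ncol(x)
  if (tt <= lag + 1L) stop("recording too short for lag ", lag, call. = FALSE)
  ctr <- rowMeans(x)
  xc <- x - ctr
  v <- apply(xc, 1L, stats::var)
  dead <- which(v < 1e-20 * max(v, 1e-300))
  if (length(dead)) {
    nm <- rownames(x)[dead] %||% as.character(dead)
    stop("zero-variance channel(s) make the covariance rank-deficient: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  c0 <- tcrossprod(xc) / tt
  eg <- eigen(c0, symmetric = TRUE)
  keep <- eg$values > rank_tol * eg$values[1]
  if (sum(keep) < 2L) {
    stop("covariance rank < 2; channels are linearly dependent", call. = FALSE)
  }
  d <- eg$values[keep]; v0 <- eg$vectors[, keep, drop = FALSE]
  wh <- diag(1 / sqrt(d), nrow = length(d)) %*% t(v0)   # k x n whitener
  z <- wh %*% xc
  c1 <- tcrossprod(z[, 1:(tt - lag), drop = FALSE],
                   z[, (1 + lag):tt, drop = FALSE]) / (tt - lag)
  cs <- (c1 + t(c1)) / 2
  eg2 <- eigen(cs, symmetric = TRUE)
  u <- eg2$vectors
  comps <- t(u) %*% z
  unmix <- t(u) %*% wh
  mixing <- v0 %*% diag(sqrt(d), nrow = length(d)) %*% u
  rownames(mixing) <- rownames(x)
  structure(list(components = comps, mixing = mixing, unmixing = unmix,
                 eigenvalues = eg2$values, center = ctr,
                 channels = rownames(x)),
            class = "amuse_decomposition")
}

#' @export
print.amuse_decomposition <- function(x, ...) {
  cat("<amuse_decomposition> ", nrow(x$components), " components from ",
      length(x$channels), " channels; lagged-covariance eigenvalues in [",
      round(min(x$eigenvalues), 3), ", ", round(max(x$eigenvalues), 3),
      "]\n", sep = "")
  invisible(x)
}

#' Reconstruct channel data from an AMUSE decomposition
#'
#' @param decomp an `amuse_decomposition`.
#' @param drop integer indices of components to zero out before
#'   reconstruction (default none).
#' @return channels x samples matrix.
#' @export
amuse_reconstruct <- function(decomp, drop = integer(0)) {
  stopifnot(inherits(decomp, "amuse_decomposition"))
  s <- decomp$components
  if (length(drop)) s[drop, ] <- 0
  decomp$mixing %*% s + decomp$center
}

#' Remove ocular-artifact components
#'
#' Flags every component whose absolute Pearson correlation with any EOG
#' proxy channel (frontal-pole electrodes by default) reaches `threshold`,
#' zeroes the flagged components and reconstructs the recording through the
#' mixing matrix.
#'
#' @param decomp an `amuse_decomposition` of `rec`.
#' @param rec the [eeg_recording] (or matrix) that was decomposed; its
#'   proxy channels provide the reference time courses.
#' @param eog_channels frontal proxy channel labels.
#' @param threshold absolute-correlation threshold (default 0.7).
#' @return the cleaned recording (same type as `rec`) with attribute
#'   `removed_components` (integer indices, possibly empty).
#' @export
remove_eog_components <- function(decomp, rec,
                                  eog_channels = c("Fp1", "Fpz", "Fp2"),
                                  threshold = 0.7) {
  stopifnot(inherits(decomp, "amuse_decomposition"))
  x <- if (inherits(rec, "eeg_recording")) rec$data else rec
  eog_channels <- intersect(eog_channels, rownames(x))
  if (!length(eog_channels)) {
    stop("no EOG proxy channels present in the recording", call. = FALSE)
  }
  proxies <- x[eog_channels, , drop = FALSE]
  r <- abs(stats::cor(t(decomp$components), t(proxies)))
  flagged <- which(apply(r, 1L, max) >= threshold)
  if (length(flagged) == nrow(decomp$components)) {
    stop("all components flagged as ocular; threshold ", threshold,
         " is likely misconfigured", call. = FALSE)
  }
  clean <- amuse_reconstruct(decomp, drop = flagged)
  if (inherits(rec, "eeg_recording")) {
    rec$data <- clean
    attr(rec, "removed_components") <- flagged
    rec
  } else {
    attr(clean, "removed_components") <- flagged
    clean
  }
}
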