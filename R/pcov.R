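#' Covariance and TIC partial covariance maps
#'
#' The plain covariance map `Cov(X_x, X_y)` between every pair of m/z
#' channels mixes genuine fragment-fragment correlations with spurious
#' all-against-all correlations driven by scan-to-scan fluctuations of the
#' total ion current (TIC).  The TIC partial covariance removes the
#' component explained by the TIC `T`:
#'
#' \deqn{pCov(x, y) = Cov(X_x, X_y) - \frac{Cov(X_x, T)\,Cov(T, X_y)}
#'   {Var(T)}}
#'
#' with sample (co)variances taken over the microscans.  Fragments born in
#' the same dissociation event remain positively correlated after the
#' correction; channels that merely ride the common-mode TIC do not.
#'
#' Because the examined channels themselves contribute to the TIC, the
#' plain `"tic"` estimator overcorrects at genuine coincidence
#' coordinates when fragment ion counts per scan are small: part of the
#' Poisson fluctuation of `X_x` and `X_y` re-enters through `T` and is
#' subtracted as if it were confound.  The default `"self"` estimator
#' removes the examined pair from its own confound regressor, using
#' `T_xy = T - X_x - X_y` in place of `T` for each map entry `(x, y)`
#' (computed in closed form from the same second moments, so the full map
#' costs the same O(n_bins^2)).  Both estimators annihilate a pure
#' common-mode ensemble exactly.
#'
#' @param ensemble A [scan_ensemble()].
#' @param estimator `"self"` (pairwise self-corrected TIC partial
#'   covariance, default), `"tic"` (classical TIC partial covariance), or
#'   `"plain"` (no confound correction).
#' @return An object of class `pcov_map`: list with `matrix` (symmetric
#'   n_bins x n_bins), `mz_grid`, `n_scans`, `estimator_params`.
#' @examples
#' # a pure common-mode ensemble maps to (numerically) zero everywhere
#' tic <- 1 + abs(rnorm(50))
#' ens <- scan_ensemble(tic %o% c(1, 2, 3), mz_grid(100, 100.6, 0.2))
#' max(abs(compute_pcov_map(ens)$matrix)) < 1e-8
#' @export
compute_pcov_map <- function(ensemble,
                             estimator = c("self", "tic", "plain")) {
  stopifnot(inherits(ensemble, "scan_ensemble"))
  estimator <- match.arg(estimator)
  X <- ensemble$intensities
  n <- nrow(X)
  if (!all(is.finite(X))) stop("non-finite intensities", call. = FALSE)
  C <- stats::cov(X)
  if (estimator != "plain") {
    tt <- ensemble$tic
    vT <- stats::var(tt)
    if (!is.finite(vT) || vT <= 0) {
      stop("degenerate TIC: Var(T) = 0, cannot partial out the confound",
           call. = FALSE)
    }
    cXT <- as.vector(stats::cov(X, tt))
    if (estimator == "tic") {
      C <- C - tcrossprod(cXT) / vT
    } else {
      # regressor T - X_x - X_y, assembled from the same second moments
      v <- diag(C)
      a <- cXT - v                      # Cov(X_x, T - X_x)
      num_x <- outer(a, rep(1, length(a))) - C  # Cov(X_x, T - X_x - X_y)
      den <- vT - 2 * outer(cXT, rep(1, length(a))) -
        2 * outer(rep(1, length(a)), cXT) +
        outer(v, rep(1, length(a))) + outer(rep(1, length(a)), v) +
        2 * C                            # Var(T - X_x - X_y)
      bad <- !is.finite(den) | den <= .Machine$double.eps * max(vT, 1)
      den[bad] <- 1
      corr <- num_x * t(num_x) / den
      corr[bad] <- 0                     # degenerate residual confound
      C <- C - corr
    }
  }
  C <- (C + t(C)) / 2  # enforce exact symmetry against fp round-off
  structure(
    list(matrix = C, mz_grid = ensemble$mz_grid, n_scans = n,
         estimator_params = list(estimator = estimator)),
    class = "pcov_map"
  )
}

#' @rdname compute_pcov_map
#' @export
compute_cov_map <- function(ensemble) compute_pcov_map(ensemble, "plain")

#' @export
print.pcov_map <- function(x, ...) {
  cat(sprintf("<pcov_map> %d x %d bins, %d scans, estimator '%s'\n",
              nrow(x$matrix), ncol(x$matrix), x$n_scans,
              x$estimator_params$estimator))
  invisible(x)
}

#' Detect candidate correlation peaks on a map
#'
#' Scans the upper triangle of the map for 8-neighbourhood local maxima
#' above a height threshold, excluding a band around the autocorrelation
#' diagonal (every channel correlates perfectly with itself).  The default
#' threshold is `5 *` the median absolute deviation of the upper-triangle
#' map values, a robust noise scale.
#'
#' @param map A [compute_pcov_map()] result.
#' @param apex_threshold Minimum apex height; `NULL` for the MAD default.
#' @param window Half-width (bins) of the square integration window used
#'   for peak volumes.
#' @param diag_exclusion Half-width (bins) of the excluded diagonal band.
#' @return Data.frame sorted by apex height (descending): `bin_x`, `bin_y`
#'   (`bin_x <= bin_y`), `mz_x`, `mz_y`, `apex_height`, `volume`.
#' @export
detect_peaks <- function(map, apex_threshold = NULL, window = 2L,
                         diag_exclusion = 3L) {
  stopifnot(inherits(map, "pcov_map"))
  M <- map$matrix
  nb <- nrow(M)
  if (!all(is.finite(M))) stop("map contains non-finite values",
                               call. = FALSE)
  if (2L * window + 1L > nb) {
    stop("integration window larger than the map", call. = FALSE)
  }
  if (is.null(apex_threshold)) {
    ut <- M[upper.tri(M)]
    apex_threshold <- 5 * stats::mad(ut, center = 0)
    if (apex_threshold <= 0) apex_threshold <- .Machine$double.eps
  }
  # 8-neighbour local maxima via shifted copies, borders excluded
  if (nb < 3L) return(.empty_peaks())
  core <- 2:(nb - 1L)
  A <- M[core, core]
  is_max <- A >= apex_threshold
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    is_max <- is_max & (A >= M[core + dx, core + dy])
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(.empty_peaks())
  bx <- hits[, 1] + 1L; by <- hits[, 2] + 1L
  keep <- bx <= by & (by - bx) >= diag_exclusion
  bx <- bx[keep]; by <- by[keep]
  if (length(bx) == 0L) return(.empty_peaks())
  vol <- vapply(seq_along(bx), function(i) {
    .window_sum(M, bx[i], by[i], window)
  }, numeric(1))
  out <- data.frame(bin_x = bx, bin_y = by,
                    mz_x = map$mz_grid[bx], mz_y = map$mz_grid[by],
                    apex_height = M[cbind(bx, by)], volume = vol)
  out <- out[order(-out$apex_height), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_peaks <- function() {
  data.frame(bin_x = integer(), bin_y = integer(), mz_x = numeric(),
             mz_y = numeric(), apex_height = numeric(), volume = numeric())
}

.window_sum <- function(M, bx, by, w) {
  nb <- nrow(M)
  xs <- max(1L, bx - w):min(nb, bx + w)
  ys <- max(1L, by - w):min(nb, by + w)
  sum(M[xs, ys])
}
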