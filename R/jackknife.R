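#' Jackknife significance scores for correlation peaks
#'
#' Scores each candidate peak as `V / sigma_JK`, where `V` is the partial
#' covariance integrated over the peak's square window and `sigma_JK` its
#' delete-one-block jackknife standard deviation: the scans are divided
#' into `n_groups` contiguous blocks, the window volume is recomputed with
#' each block left out, and
#' \deqn{\sigma_{JK} = \sqrt{\frac{g-1}{g} \sum_j
#'   (V_{(-j)} - \bar V_{(-)})^2}.}
#' A genuine fragment-fragment correlation yields a volume that is stable
#' under resampling (large score); a noise ripple does not.
#'
#' The window volume collapses to scalar statistics: with
#' `u = sum over window rows`, `v = sum over window columns` of the
#' per-scan intensities, `V = Cov(u, v) - Cov(u, T) Cov(v, T) / Var(T)`
#' (with the regressor replaced by `T - u - v` for the `"self"`
#' estimator), so every leave-one-out recomputation costs O(1) from
#' per-block sums.
#'
#' @param ensemble A [scan_ensemble()].
#' @param peaks Data.frame with `bin_x`, `bin_y` columns (e.g. from
#'   [detect_peaks()], or arbitrary coordinates to score a null set).
#' @param n_groups Number of contiguous jackknife blocks (>= 2); capped at
#'   the number of scans.
#' @param window Half-width (bins) of the square integration window.
#' @param estimator Covariance estimator, as in [compute_pcov_map()]; the
#'   `"self"` default uses `T - u - v` (TIC minus the two windows) as the
#'   confound regressor.
#' @return `peaks` with columns `volume`, `sigma_jk`, `score` added,
#'   sorted by score (descending).  A perfectly stable volume
#'   (`sigma_jk = 0`) is reported as `Inf` with a warning, never as a
#'   silent division.
#' @export
jackknife_score <- function(ensemble, peaks, n_groups = 100L,
                            window = 2L,
                            estimator = c("self", "tic", "plain")) {
  estimator <- match.arg(estimator)
  jk <- .jackknife_volumes(ensemble, peaks, n_groups, window, estimator)
  if (nrow(peaks) == 0L) {
    peaks$volume <- numeric(0); peaks$sigma_jk <- numeric(0)
    peaks$score <- numeric(0)
    return(peaks)
  }
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    .jk_ratio(jk$vfull[i], jk$vj[, i],
              sprintf("peak (%d, %d)", peaks$bin_x[i], peaks$bin_y[i]))
  })
  peaks$volume <- jk$vfull
  peaks$sigma_jk <- vapply(res, `[[`, numeric(1), "sigma")
  peaks$score <- vapply(res, `[[`, numeric(1), "score")
  peaks <- peaks[order(-peaks$score), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Composite marker correlation score per isomer
#'
#' Sums the map volumes of *all* of an isomer's marker correlation pairs
#' into one composite volume and jackknifes the sum.  Coincidence signal
#' accumulates linearly over an isomer's markers while resampling noise
#' accumulates in quadrature, so the composite separates present from
#' absent isomers more sharply than any single marker when individual
#' marker correlations are weak; for an absent isomer the composite score
#' behaves like a single standard-normal deviate rather than the maximum
#' over many marker scores.
#'
#' @inheritParams jackknife_score
#' @param marker_pairs A [marker_table()] data.frame (`isomer`, `mz_x`,
#'   `mz_y`); coordinates are mapped to the nearest map bins.
#' @return Data.frame, one row per isomer: `isomer`, `n_markers`,
#'   `volume` (composite), `sigma_jk`, `score`.
#' @export
composite_marker_score <- function(ensemble, marker_pairs,
                                   n_groups = 100L, window = 2L,
                                   estimator = c("self", "tic",
                                                 "plain")) {
  estimator <- match.arg(estimator)
  grid <- ensemble$mz_grid
  bx <- .mz_to_bin(grid, marker_pairs$mz_x)
  by <- .mz_to_bin(grid, marker_pairs$mz_y)
  ok <- !is.na(bx) & !is.na(by)
  labs <- unique(marker_pairs$isomer)
  out <- data.frame(isomer = labs, n_markers = NA_integer_,
                    volume = NA_real_, sigma_jk = NA_real_,
                    score = NA_real_)
  for (r in seq_along(labs)) {
    sel <- which(ok & marker_pairs$isomer == labs[r])
    out$n_markers[r] <- length(sel)
    if (length(sel) == 0L) next
    jk <- .jackknife_volumes(
      ensemble, data.frame(bin_x = bx[sel], bin_y = by[sel]),
      n_groups, window, estimator)
    comp <- .jk_ratio(sum(jk$vfull), rowSums(jk$vj),
                      paste("isomer", labs[r]))
    out$volume[r] <- sum(jk$vfull)
    out$sigma_jk[r] <- comp$sigma
    out$score[r] <- comp$score
  }
  out
}

# leave-one-block-out window volumes for a set of map coordinates:
# returns vfull (length p) and vj (g x p matrix of delete-one volumes)
.jackknife_volumes <- function(ensemble, peaks, n_groups, window,
                               estimator) {
  stopifnot(inherits(ensemble, "scan_ensemble"))
  X <- ensemble$intensities
  tt <- ensemble$tic
  n <- nrow(X)
  nb <- ncol(X)
  g <- min(as.integer(n_groups), n)
  if (g < 2L) stop("need at least 2 jackknife groups", call. = FALSE)
  p <- nrow(peaks)
  if (p == 0L) return(list(vfull = numeric(0),
                           vj = matrix(0, g, 0)))
  block <- as.integer(cut(seq_len(n), g, labels = FALSE))
  n_j <- tabulate(block, g)
  sT <- as.vector(rowsum(tt, block))
  sT2 <- as.vector(rowsum(tt * tt, block))
  vfull <- numeric(p)
  vj <- matrix(0, g, p)
  for (i in seq_len(p)) {
    xs <- max(1L, peaks$bin_x[i] - window):min(nb, peaks$bin_x[i] + window)
    ys <- max(1L, peaks$bin_y[i] - window):min(nb, peaks$bin_y[i] + window)
    u <- rowSums(X[, xs, drop = FALSE])
    v <- rowSums(X[, ys, drop = FALSE])
    S <- rowsum(cbind(u, v, u * v, u * u, v * v, u * tt, v * tt), block)
    tot <- colSums(S)
    vfull[i] <- .pcov_scalar(tot[1], tot[2], tot[3], tot[4], tot[5],
                             tot[6], tot[7], sum(sT), sum(sT2), n,
                             estimator)
    for (j in seq_len(g)) {
      vj[j, i] <- .pcov_scalar(
        tot[1] - S[j, 1], tot[2] - S[j, 2], tot[3] - S[j, 3],
        tot[4] - S[j, 4], tot[5] - S[j, 5], tot[6] - S[j, 6],
        tot[7] - S[j, 7], sum(sT) - sT[j], sum(sT2) - sT2[j],
        n - n_j[j], estimator)
    }
  }
  list(vfull = vfull, vj = vj)
}

# V / sigma_JK with the zero-sigma sentinel
.jk_ratio <- function(vfull, vj, what) {
  g <- length(vj)
  sigma <- sqrt((g - 1) / g * sum((vj - mean(vj))^2))
  score <- if (sigma > 0) vfull / sigma else {
    warning("jackknife sigma is zero for ", what,
            "; score reported as Inf", call. = FALSE)
    if (vfull >= 0) Inf else -Inf
  }
  list(sigma = sigma, score = score)
}

# windowed partial covariance from sufficient statistics over a scan subset
.pcov_scalar <- function(su, sv, suv, suu, svv, suT, svT, sT, sT2, n,
                         estimator) {
  if (n < 2L) return(NA_real_)
  cuv <- (suv - su * sv / n) / (n - 1)
  if (estimator == "plain") return(cuv)
  vT <- (sT2 - sT * sT / n) / (n - 1)
  cuT <- (suT - su * sT / n) / (n - 1)
  cvT <- (svT - sv * sT / n) / (n - 1)
  if (estimator == "self") {
    vu <- (suu - su * su / n) / (n - 1)
    vv <- (svv - sv * sv / n) / (n - 1)
    vT <- vT - 2 * cuT - 2 * cvT + vu + vv + 2 * cuv
    cuT <- cuT - vu - cuv   # Cov(u, T - u - v)
    cvT <- cvT - vv - cuv
  }
  if (!is.finite(vT) || vT <= .Machine$double.eps * max(1, sT2 / n)) {
    return(cuv)  # degenerate residual confound: nothing to partial out
  }
  cuv - cuT * cvT / vT
}
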