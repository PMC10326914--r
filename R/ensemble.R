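#' Microscan ensembles on a common m/z grid
#'
#' A `scan_ensemble` stacks repeated MS/MS microscans, binned onto a shared
#' uniform m/z grid, together with each scan's total ion current (TIC).
#' The scan-to-scan intensity fluctuations across the ensemble are the
#' statistical signal that partial covariance mapping exploits; the TIC is
#' the common-mode confound it removes.
#'
#' @param intensities Non-negative matrix, scans in rows, m/z bins in
#'   columns.
#' @param mz_grid Strictly increasing, uniformly spaced bin centers (Th).
#' @param tic Per-scan total ion current; defaults to the row sums.  Supply
#'   the full-spectrum TIC when the grid covers only a map region.
#' @param metadata Free-form acquisition notes (list).
#' @return An object of class `scan_ensemble`.
#' @export
scan_ensemble <- function(intensities, mz_grid, tic = NULL,
                          metadata = list()) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) < 2L) {
    stop("an ensemble needs at least 2 microscans", call. = FALSE)
  }
  if (ncol(intensities) != length(mz_grid)) {
    stop("mz_grid length must match intensity columns", call. = FALSE)
  }
  d <- diff(mz_grid)
  if (length(d) && (any(d <= 0) ||
                    max(abs(d - d[1])) > 1e-6 * abs(d[1]))) {
    stop("mz_grid must be strictly increasing and uniform", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (is.null(tic)) tic <- rowSums(intensities)
  if (length(tic) != nrow(intensities)) {
    stop("tic length must equal the number of scans", call. = FALSE)
  }
  if (sum(tic > 0) < 2L) {
    stop("at least two scans must carry signal (tic > 0)", call. = FALSE)
  }
  structure(
    list(intensities = unname(intensities), mz_grid = as.numeric(mz_grid),
         tic = as.numeric(tic), metadata = metadata),
    class = "scan_ensemble"
  )
}

#' @export
print.scan_ensemble <- function(x, ...) {
  cat(sprintf(
    "<scan_ensemble> %d scans x %d bins, m/z %.2f-%.2f (bin %.3g Th)\n",
    nrow(x$intensities), ncol(x$intensities), min(x$mz_grid),
    max(x$mz_grid), if (length(x$mz_grid) > 1) diff(x$mz_grid[1:2]) else NA))
  invisible(x)
}

#' @rdname scan_ensemble
#' @export
n_scans <- function(x) nrow(x$intensities)

#' Uniform m/z grid specification
#'
#' @param mz_min,mz_max Grid range in Th.
#' @param bin_width Bin width in Th (default 0.2, roughly matching
#'   unit-resolution ion-trap peak spacing).
#' @return Numeric vector of bin centers spanning `[mz_min, mz_max]`.
#' @export
mz_grid <- function(mz_min, mz_max, bin_width = 0.2) {
  stopifnot(mz_max > mz_min, bin_width > 0)
  seq(mz_min + bin_width / 2, mz_max, by = bin_width)
}

# nearest-bin index for m/z values; NA outside the grid edges
.mz_to_bin <- function(grid, mz) {
  bw <- diff(grid[1:2])
  idx <- round((mz - grid[1]) / bw) + 1L
  idx[idx < 1L | idx > length(grid)] <- NA_integer_
  as.integer(idx)
}
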