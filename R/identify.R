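#' Theoretical marker correlation table
#'
#' Flattens a 2D [find_unique_markers()] report into a table of candidate
#' marker pairs suitable for [match_markers()], optionally keeping only
#' pairs whose both coordinates fall inside the acquired map region.
#'
#' @param report A `marker_report` with `mode == "2d"`.
#' @param mz_range Optional `c(min, max)` window (Th) both pair
#'   coordinates must lie in.
#' @param min_separation Minimum `mz_y - mz_x` gap (Th); pairs of two
#'   distinct fragments sharing one m/z value fall on the map's excluded
#'   autocorrelation diagonal and cannot be interrogated, so they are
#'   dropped by default.
#' @return Data.frame `isomer`, `mz_x`, `mz_y` (`mz_x <= mz_y`).
#' @export
marker_table <- function(report, mz_range = NULL, min_separation = 1) {
  stopifnot(inherits(report, "marker_report"), report$mode == "2d")
  rows <- lapply(names(report$unique), function(lab) {
    u <- report$unique[[lab]]
    if (nrow(u) == 0L) return(NULL)
    data.frame(isomer = lab, mz_x = u$mz_lo, mz_y = u$mz_hi)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(isomer = character(), mz_x = numeric(),
                      mz_y = numeric()))
  }
  out <- out[out$mz_y - out$mz_x >= min_separation, , drop = FALSE]
  if (!is.null(mz_range)) {
    keep <- out$mz_x >= mz_range[1] & out$mz_x <= mz_range[2] &
      out$mz_y >= mz_range[1] & out$mz_y <= mz_range[2]
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Match scored correlation peaks to theoretical marker pairs
#'
#' Assigns to each theoretical marker correlation the nearest scored peak
#' lying within `tolerance` on both m/z coordinates (ties broken towards
#' the higher-scoring peak).  An isomer is called present when at least one
#' of its marker pairs matches a peak at or above `score_threshold`.
#'
#' @param peaks Scored peaks from [jackknife_score()] (columns `mz_x`,
#'   `mz_y`, `volume`, `score`).
#' @param marker_pairs A [marker_table()] data.frame (`isomer`, `mz_x`,
#'   `mz_y`).
#' @param tolerance Peak-to-marker match tolerance in Th (per coordinate);
#'   default 0.3 Th for unit-resolution ion-trap data.
#' @param score_threshold Minimum jackknife score for a match to count as
#'   evidence.  There is no universal value; 5 (a five-sigma-like
#'   stability requirement) is a conservative default for ~100-block
#'   jackknives on 10^4-scan ensembles.
#' @return An object of class `isomer_evidence`: list with `markers` (one
#'   row per marker pair: match coordinates, `volume`, `score`,
#'   `detected`) and `summary` (one row per isomer: `n_markers`,
#'   `n_detected`, `best_score`, `volume` of the best-scoring detected
#'   marker, `present`).
#' @export
match_markers <- function(peaks, marker_pairs, tolerance = 0.3,
                          score_threshold = 5) {
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  mk <- marker_pairs
  n <- nrow(mk)
  mk$peak_mz_x <- rep(NA_real_, n)
  mk$peak_mz_y <- rep(NA_real_, n)
  mk$volume <- rep(NA_real_, n)
  mk$score <- rep(NA_real_, n)
  mk$detected <- logical(n)
  if (n > 0L && nrow(peaks) > 0L) {
    for (i in seq_len(n)) {
      dx <- abs(peaks$mz_x - mk$mz_x[i])
      dy <- abs(peaks$mz_y - mk$mz_y[i])
      ok <- which(dx <= tolerance & dy <= tolerance)
      if (length(ok) == 0L) next
      d <- pmax(dx[ok], dy[ok])
      # nearest peak; among equidistant candidates prefer the higher score
      best <- ok[order(d, -peaks$score[ok])][1L]
      mk$peak_mz_x[i] <- peaks$mz_x[best]
      mk$peak_mz_y[i] <- peaks$mz_y[best]
      mk$volume[i] <- peaks$volume[best]
      mk$score[i] <- peaks$score[best]
      mk$detected[i] <- is.finite(peaks$score[best]) &&
        peaks$score[best] >= score_threshold
    }
  }
  labs <- unique(marker_pairs$isomer)
  summary <- do.call(rbind, lapply(labs, function(lab) {
    rows <- mk[mk$isomer == lab, , drop = FALSE]
    det <- rows[rows$detected, , drop = FALSE]
    best <- if (nrow(det)) det[which.max(det$score), ] else NULL
    data.frame(isomer = lab, n_markers = nrow(rows),
               n_detected = nrow(det),
               best_score = if (nrow(rows)) suppressWarnings(
                 max(rows$score, na.rm = TRUE)) else NA_real_,
               volume = if (is.null(best)) NA_real_ else best$volume,
               present = nrow(det) > 0L)
  }))
  if (is.null(summary)) {
    summary <- data.frame(isomer = character(), n_markers = integer(),
                          n_detected = integer(), best_score = numeric(),
                          volume = numeric(), present = logical())
  } else {
    summary$best_score[!is.finite(summary$best_score)] <- NA_real_
  }
  rownames(summary) <- NULL
  structure(list(markers = mk, summary = summary,
                 tolerance = tolerance,
                 score_threshold = score_threshold),
            class = "isomer_evidence")
}

#' @export
print.isomer_evidence <- function(x, ...) {
  cat(sprintf("<isomer_evidence> tolerance %.2f Th, score threshold %g\n",
              x$tolerance, x$score_threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Identify isomers in a microscan ensemble via marker correlations
#'
#' The full identification pipeline: compute the partial covariance map,
#' detect candidate correlation peaks, jackknife-score the candidates
#' lying near any theoretical marker pair (scoring is restricted to those
#' neighbourhoods; the map can hold thousands of candidate ripples), and
#' match scored peaks to the marker table.
#'
#' @param ensemble A [scan_ensemble()].
#' @param marker_pairs A [marker_table()] data.frame.  For experimental
#'   matching the marker uniqueness should have been established at the
#'   same tolerance used here (see [find_unique_markers()]), otherwise
#'   near-degenerate pairs of other isomers can masquerade as markers.
#' Presence calls combine evidence over *all* of an isomer's marker
#' pairs via [composite_marker_score()]: an isomer is reported present
#' when its composite jackknife score reaches `score_threshold`.  The
#' per-marker peak matches (Fig.-2-style single correlations) are
#' retained in the `markers` element and drive the `n_detected` counts.
#'
#' @inheritParams match_markers
#' @inheritParams jackknife_score
#' @param diag_exclusion,apex_threshold Passed to [detect_peaks()].
#' @return An `isomer_evidence` object (see [match_markers()]) whose
#'   `summary` additionally carries `composite_volume` and
#'   `composite_score`; `present` is the composite call.
#' @export
identify_isomers <- function(ensemble, marker_pairs, tolerance = 0.3,
                             score_threshold = 5, n_groups = 100L,
                             window = 2L, diag_exclusion = 3L,
                             apex_threshold = NULL,
                             estimator = c("self", "tic", "plain")) {
  estimator <- match.arg(estimator)
  map <- compute_pcov_map(ensemble, estimator = estimator)
  peaks <- detect_peaks(map, apex_threshold = apex_threshold,
                        window = window, diag_exclusion = diag_exclusion)
  if (nrow(peaks) > 0L && nrow(marker_pairs) > 0L) {
    near <- vapply(seq_len(nrow(peaks)), function(i) {
      any(abs(peaks$mz_x[i] - marker_pairs$mz_x) <= tolerance &
            abs(peaks$mz_y[i] - marker_pairs$mz_y) <= tolerance)
    }, logical(1))
    peaks <- peaks[near, , drop = FALSE]
  }
  peaks <- jackknife_score(ensemble, peaks, n_groups = n_groups,
                           window = window, estimator = estimator)
  ev <- match_markers(peaks, marker_pairs, tolerance = tolerance,
                      score_threshold = score_threshold)
  comp <- composite_marker_score(ensemble, marker_pairs,
                                 n_groups = n_groups, window = window,
                                 estimator = estimator)
  idx <- match(ev$summary$isomer, comp$isomer)
  ev$summary$composite_volume <- comp$volume[idx]
  ev$summary$composite_score <- comp$score[idx]
  ev$summary$present <- !is.na(comp$score[idx]) &
    comp$score[idx] >= score_threshold
  ev
}

#' Relative quantification from marker correlation volumes
#'
#' The volume of a fragment-fragment correlation peak scales linearly with
#' the concentration of its precursor, so the volumes of one marker
#' correlation per isomer estimate the isomers' relative abundances
#' directly (assuming comparable fragmentation efficiency of the
#' interrogated channels).
#'
#' @param evidence An [match_markers()] result (or a data.frame with
#'   `isomer` and `volume` columns).
#' @return Data.frame `isomer`, `volume`, `fraction` with fractions
#'   normalised to sum to 1 over the isomers with detected evidence.
#' @export
relative_quantify <- function(evidence) {
  s <- if (inherits(evidence, "isomer_evidence")) {
    evidence$summary[evidence$summary$present, c("isomer", "volume")]
  } else {
    evidence[c("isomer", "volume")]
  }
  if (nrow(s) == 0L || !any(is.finite(s$volume) & s$volume > 0)) {
    stop("no positive marker correlation volumes to quantify",
         call. = FALSE)
  }
  if (any(!is.finite(s$volume) | s$volume <= 0)) {
    stop("every quantified isomer needs a positive marker volume",
         call. = FALSE)
  }
  s$fraction <- s$volume / sum(s$volume)
  rownames(s) <- NULL
  s
}
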