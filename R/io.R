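#' Read and write microscan ensembles in the plain-text scan dialect
#'
#' The dialect is one block per microscan: a header line `SCAN <index>`,
#' followed by one `<mz><TAB><intensity>` line per point with m/z
#' ascending, blocks separated by blank lines; lines starting with `#` are
#' comments.  `read_scans()` bins every point onto the supplied uniform
#' grid (summing intensities within a bin; points outside the grid are
#' kept out of the matrix but still count towards the scan's TIC).
#' `write_scans()` emits the non-empty bins of an ensemble, so a
#' write-read cycle on the same grid is lossless.
#'
#' @param path File path.
#' @param grid Bin centers from [mz_grid()].
#' @return `read_scans()` returns a [scan_ensemble()].
#' @export
read_scans <- function(path, grid) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines)
  scans <- list()
  cur_mz <- cur_int <- NULL
  cur_id <- NA_character_
  flush <- function() {
    if (!is.null(cur_mz)) {
      if (is.unsorted(cur_mz, strictly = FALSE)) {
        stop("non-monotone m/z in scan ", cur_id, call. = FALSE)
      }
      scans[[length(scans) + 1L]] <<- list(mz = cur_mz, int = cur_int)
    }
  }
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^SCAN\\b", ln)) {
      flush()
      cur_id <- sub("^SCAN\\s*", "", ln)
      cur_mz <- numeric(0); cur_int <- numeric(0)
      next
    }
    if (is.null(cur_mz)) {
      stop(sprintf("line %d: data before any SCAN header", i),
           call. = FALSE)
    }
    parts <- strsplit(ln, "[\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || anyNA(vals)) {
      stop(sprintf("line %d: malformed data line '%s'", i, lines[i]),
           call. = FALSE)
    }
    if (vals[2] < 0) {
      stop(sprintf("line %d: negative intensity", i), call. = FALSE)
    }
    cur_mz <- c(cur_mz, vals[1]); cur_int <- c(cur_int, vals[2])
  }
  flush()
  if (length(scans) == 0L) stop("no scans in ", path, call. = FALSE)
  nb <- length(grid)
  X <- matrix(0, length(scans), nb)
  tic <- numeric(length(scans))
  for (s in seq_along(scans)) {
    tic[s] <- sum(scans[[s]]$int)
    bins <- .mz_to_bin(grid, scans[[s]]$mz)
    ok <- !is.na(bins)
    if (any(ok)) {
      acc <- tapply(scans[[s]]$int[ok], bins[ok], sum)
      X[s, as.integer(names(acc))] <- acc
    }
  }
  scan_ensemble(X, grid, tic = tic, metadata = list(source = path))
}

#' @rdname read_scans
#' @param ensemble A [scan_ensemble()] to write.
#' @param digits Significant digits for intensities.
#' @export
write_scans <- function(ensemble, path, digits = 8L) {
  stopifnot(inherits(ensemble, "scan_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# microscan ensemble, pcovms scan text dialect", con)
  X <- ensemble$intensities
  for (s in seq_len(nrow(X))) {
    writeLines(sprintf("SCAN %d", s), con)
    nz <- which(X[s, ] > 0)
    if (length(nz)) {
      writeLines(sprintf("%.6f\t%.*g", ensemble$mz_grid[nz], digits,
                         X[s, nz]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Build a mixture model from a YAML config file
#'
#' Expected layout:
#' ```
#' grid: {min: 480, max: 560, bin_width: 0.2}
#' tic_fluctuation: 0.3
#' noise_sd: 0.01
#' peak_width: 0.05
#' components:
#'   - label: P4
#'     lambda: 25
#'     channels:
#'       - probability: 0.45
#'         products:
#'           - {mz: 512.2827, yield: 0.5}
#'           - {mz: 530.3045, yield: 0.5}
#' ```
#'
#' @param path YAML file path.
#' @return A [mixture_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$grid
  if (is.null(g)) stop("model config needs a 'grid' entry", call. = FALSE)
  grid <- mz_grid(g$min, g$max, if (is.null(g$bin_width)) 0.2
                  else g$bin_width)
  comps <- lapply(cfg$components, function(cc) {
    chans <- lapply(cc$channels, function(ch) {
      prods <- do.call(rbind, lapply(ch$products, function(p) {
        data.frame(mz = as.numeric(p$mz), yield = as.numeric(p$yield))
      }))
      fragmentation_channel(prods, as.numeric(ch$probability))
    })
    list(label = if (is.null(cc$label)) "component" else cc$label,
         lambda = as.numeric(cc$lambda), channels = chans)
  })
  mixture_model(
    comps, grid = grid,
    tic_fluctuation = if (is.null(cfg$tic_fluctuation)) 0.3
                      else cfg$tic_fluctuation,
    noise_sd = if (is.null(cfg$noise_sd)) 0.01 else cfg$noise_sd,
    peak_width = if (is.null(cfg$peak_width)) 0.05 else cfg$peak_width
  )
}

#' Write a data.frame as a canonical TSV report
#'
#' Fixed header, tab separation, no quoting or row names -- the schema
#' used by every command-line report.
#'
#' @param x Data.frame.
#' @param path Output path.
#' @export
write_report_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
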