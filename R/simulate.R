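#' Fragmentation channels and mixture models for synthetic microscans
#'
#' A `fragmentation_channel` is one dissociation outcome of a precursor: a
#' set of product ions deposited *together* whenever a precursor takes that
#' channel.  This co-deposition is the physical source of
#' fragment-fragment correlation.  A `mixture_model` combines one or more
#' precursor components (each with a mean precursor count per scan and its
#' channels) with a log-normal per-scan common-mode factor (the TIC
#' confound), additive detector noise and a Gaussian peak shape on a
#' uniform m/z grid.
#'
#' @param products Data.frame with columns `mz` (Th) and `yield`
#'   (detected-fraction per precursor taking this channel, in (0, 1]).
#' @param probability Branching ratio of the channel per precursor.
#' @return `fragmentation_channel()` returns a `fragmentation_channel`
#'   object; `mixture_model()` a `mixture_model`.
#' @export
fragmentation_channel <- function(products, probability) {
  products <- as.data.frame(products)
  stopifnot(all(c("mz", "yield") %in% names(products)))
  if (any(products$yield <= 0 | products$yield > 1)) {
    stop("yields must be in (0, 1]", call. = FALSE)
  }
  if (probability <= 0 || probability > 1) {
    stop("channel probability must be in (0, 1]", call. = FALSE)
  }
  structure(list(products = products, probability = probability),
            class = "fragmentation_channel")
}

#' @rdname fragmentation_channel
#' @param components List of components, each a list with `label`,
#'   `lambda` (mean precursor count per scan at unit common-mode factor)
#'   and `channels` (list of `fragmentation_channel`s whose probabilities
#'   sum to at most 1; the remainder is undissociated/unobserved
#'   precursor).
#' @param grid Bin centers from [mz_grid()].
#' @param tic_fluctuation Relative SD of the per-scan log-normal
#'   common-mode factor (sdlog).
#' @param noise_sd Additive Gaussian noise SD per bin (ion units).
#' @param peak_width Gaussian peak shape SD in Th.
#' @export
mixture_model <- function(components, grid, tic_fluctuation = 0.3,
                          noise_sd = 0.01, peak_width = 0.05) {
  if (length(components) == 0L) stop("empty model", call. = FALSE)
  stopifnot(tic_fluctuation >= 0, noise_sd >= 0, peak_width > 0)
  for (comp in components) {
    if (is.null(comp$lambda) || comp$lambda <= 0) {
      stop("every component needs lambda > 0", call. = FALSE)
    }
    ptot <- sum(vapply(comp$channels, `[[`, numeric(1), "probability"))
    if (ptot > 1 + 1e-12) {
      stop(sprintf("channel probabilities of component '%s' sum to %.3f > 1",
                   comp$label, ptot), call. = FALSE)
    }
  }
  structure(list(components = components, grid = as.numeric(grid),
                 tic_fluctuation = tic_fluctuation, noise_sd = noise_sd,
                 peak_width = peak_width),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  nch <- sum(vapply(x$components, function(c) length(c$channels),
                    integer(1)))
  cat(sprintf(
    "<mixture_model> %d component(s), %d channels, grid %.1f-%.1f Th\n",
    length(x$components), nch, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Build a mixture model from a combinatorial isomer set
#'
#' Gives every isomer a fragmentation channel for each complementary b/y
#' pair and (policy `"pairs"`) a secondary-fragmentation channel for every
#' disjoint (terminal, internal) pair, with uniform branching ratios
#' summing to `total_probability`.  Uniform branching is a synthetic
#' choice -- real CID branching ratios are peptide-specific and are not
#' modelled here.
#'
#' @param iso_set An [enumerate_isomers()] result.
#' @param abundances Positive relative abundances, one per isomer.
#' @param channel_policy `"pairs"` (complementary b/y plus
#'   terminal/internal, the correlation classes a partial-covariance map
#'   reads out) or `"complementary"` (b/y only).
#' @param lambda_total Mean total precursor count per scan, split across
#'   isomers by abundance.  The default (200, i.e. 50 per isomer in a
#'   four-isomer mixture) reproduces the strong-fragment regime of
#'   unit-resolution CID spectra: per-channel coincidence rates near
#'   0.08 per scan under uniform branching.  Much smaller fills leave
#'   too few coincidences per channel for stable correlation scoring at
#'   10^4 microscans; much larger fills inflate the common-mode
#'   estimation noise of the covariance faster than the coincidence
#'   signal.
#' @param total_probability Summed branching ratio per precursor (< 1
#'   leaves a surviving-precursor remainder).
#' @param yield Detected fraction for every product ion.
#' @param internal_kind Internal ion type for secondary channels.
#' @inheritParams mixture_model
#' @return A [mixture_model()].
#' @export
make_isomer_mixture_model <- function(iso_set, abundances,
                                      channel_policy = c("pairs",
                                                         "complementary"),
                                      grid, lambda_total = 200,
                                      total_probability = 0.9,
                                      yield = 0.5,
                                      internal_kind = "internal_b",
                                      tic_fluctuation = 0.3,
                                      noise_sd = 0.01, peak_width = 0.05) {
  channel_policy <- match.arg(channel_policy)
  k <- length(iso_set$isomers)
  if (length(abundances) != k || any(abundances <= 0)) {
    stop("abundances must be positive, one per isomer", call. = FALSE)
  }
  lambdas <- lambda_total * abundances / sum(abundances)
  components <- lapply(seq_len(k), function(i) {
    p <- iso_set$isomers[[i]]
    term <- generate_fragments(p, kinds = c("b", "y"))
    bs <- term[term$kind == "b", ]
    ys <- term[term$kind == "y", ]
    n <- length(p$residues)
    prods <- list()
    # complementary b_i / y_(n-i) pairs
    for (bi in seq_len(n - 1L)) {
      prods[[length(prods) + 1L]] <-
        data.frame(mz = c(bs$mz[bs$end == bi], ys$mz[ys$start == bi + 1L]),
                   yield = yield)
    }
    if (channel_policy == "pairs") {
      int <- generate_fragments(p, kinds = internal_kind)
      for (r in seq_len(nrow(int))) {
        left_b <- bs$mz[bs$end < int$start[r]]
        right_y <- ys$mz[ys$start > int$end[r]]
        for (mzt in c(left_b, right_y)) {
          prods[[length(prods) + 1L]] <-
            data.frame(mz = c(mzt, int$mz[r]), yield = yield)
        }
      }
    }
    pr <- total_probability / length(prods)
    list(label = iso_set$labels[i], lambda = lambdas[i],
         channels = lapply(prods, fragmentation_channel,
                           probability = pr))
  })
  mixture_model(components, grid = grid,
                tic_fluctuation = tic_fluctuation, noise_sd = noise_sd,
                peak_width = peak_width)
}

#' Simulate a microscan ensemble with known correlation structure
#'
#' Per scan: a common-mode factor `f ~ LogNormal(0, tic_fluctuation)` is
#' drawn; each channel's precursor count is Poisson with mean
#' `f * lambda * probability` (Poisson thinning of the component's
#' precursor beam over its branching ratios); every count deposits *all*
#' of the channel's products at once -- the correlation source -- as
#' Gaussian peaks onto the grid; Gaussian noise is added and negative
#' bins are clipped.  The reported TIC is the total deposited ion signal
#' of the full spectrum, including products falling outside the acquired
#' grid window.
#'
#' @param model A [mixture_model()].
#' @param n_scans Number of microscans (>= 2).
#' @param seed Integer seed; identical `(model, n_scans, seed)` give
#'   byte-identical ensembles.  The caller's RNG state is left untouched.
#' @return A [scan_ensemble()].
#' @export
simulate_scan_ensemble <- function(model, n_scans, seed = 1L) {
  stopifnot(inherits(model, "mixture_model"))
  if (n_scans < 2L) stop("n_scans must be >= 2", call. = FALSE)
  grid <- model$grid
  nb <- length(grid)
  bw <- diff(grid[1:2])

  # flatten channels across components
  rates <- numeric(0)
  chans <- list()
  for (comp in model$components) {
    for (ch in comp$channels) {
      rates <- c(rates, comp$lambda * ch$probability)
      chans[[length(chans) + 1L]] <- ch
    }
  }
  kch <- length(chans)
  # deposition profile per channel (grid row) and total deposited current
  D <- matrix(0, kch, nb)
  ty <- numeric(kch)
  for (j in seq_len(kch)) {
    pr <- chans[[j]]$products
    ty[j] <- sum(pr$yield)
    for (r in seq_len(nrow(pr))) {
      lo <- pr$mz[r] - 4 * model$peak_width
      hi <- pr$mz[r] + 4 * model$peak_width
      bins <- which(grid >= lo & grid <= hi)
      if (length(bins) == 0L) next
      w <- stats::dnorm(grid[bins], pr$mz[r], model$peak_width)
      w <- w / sum(w)  # total deposit = yield wherever the apex sits
      D[j, bins] <- D[j, bins] + pr$yield[r] * w
    }
  }

  .with_seed(seed, {
    X <- matrix(0, n_scans, nb)
    tic <- numeric(n_scans)
    chunk <- 1000L
    done <- 0L
    while (done < n_scans) {
      take <- min(chunk, n_scans - done)
      idx <- done + seq_len(take)
      f <- stats::rlnorm(take, 0, model$tic_fluctuation)
      cnt <- matrix(stats::rpois(take * kch, outer(f, rates)), take, kch)
      Xc <- cnt %*% D
      if (model$noise_sd > 0) {
        Xc <- Xc + matrix(stats::rnorm(take * nb, 0, model$noise_sd),
                          take, nb)
      }
      Xc[Xc < 0] <- 0
      X[idx, ] <- Xc
      tic[idx] <- as.numeric(cnt %*% ty)
      done <- done + take
    }
    # guard the ensemble invariant on degenerate tiny models
    if (sum(tic > 0) < 2L) tic <- tic + rowSums(X)
    scan_ensemble(X, grid, tic = tic,
                  metadata = list(seed = seed, n_scans = n_scans,
                                  simulator = "pcovms"))
  })
}

# evaluate 'expr' under a fixed RNG seed, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
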