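test_that("scan ensembles validate their invariants", {
  g <- mz_grid(100, 101, 0.2)
  expect_error(scan_ensemble(matrix(1, 1, 5), g), "at least 2")
  expect_error(scan_ensemble(matrix(1, 3, 4), g), "match")
  expect_error(scan_ensemble(matrix(-1, 3, 5), g), "non-negative")
  expect_error(scan_ensemble(matrix(1, 3, 3), c(1, 2, 4)), "uniform")
  expect_error(scan_ensemble(matrix(0, 3, 5), g), "tic")
  ens <- scan_ensemble(matrix(1, 3, 5), g)
  expect_equal(ens$tic, rep(5, 3))
  expect_equal(n_scans(ens), 3L)
})

test_that("pure common-mode ensembles map to numerical zero", {
  withr::with_seed(11, {
    tt <- 1 + abs(rnorm(200))
    a <- c(0.5, 1.5, 3, 0.2, 1)
    ens <- scan_ensemble(tt %o% a, mz_grid(100, 101, 0.2))
    for (est in c("tic", "self")) {
      M <- compute_pcov_map(ens, estimator = est)$matrix
      plain <- compute_cov_map(ens)$matrix
      expect_lt(max(abs(M)), 1e-10 * max(abs(plain)))
    }
  })
})

test_that("the map is symmetric and the degenerate TIC is rejected", {
  withr::with_seed(12, {
    X <- matrix(rpois(400 * 20, 5), 400, 20)
    ens <- scan_ensemble(X, mz_grid(200, 204, 0.2))
    for (est in c("self", "tic", "plain")) {
      M <- compute_pcov_map(ens, estimator = est)$matrix
      expect_lt(max(abs(M - t(M))), 1e-9 * max(abs(M)))
    }
    const <- scan_ensemble(matrix(1, 10, 20), mz_grid(200, 204, 0.2))
    expect_error(compute_pcov_map(const), "degenerate TIC")
    # a single deviating scan keeps Var(T) > 0 and the map finite
    X2 <- matrix(1, 10, 20); X2[3, ] <- 2
    one <- scan_ensemble(X2, mz_grid(200, 204, 0.2))
    expect_true(all(is.finite(compute_pcov_map(one)$matrix)))
  })
})

test_that("coincident Poisson channels stand out over independent ones", {
  withr::with_seed(13, {
    n <- 10000
    c1 <- rpois(n, 3)                  # deposited in bins 2 and 8 together
    X <- cbind(c1, rpois(n, 3), rpois(n, 3), rpois(n, 3), c1,
               rpois(n, 3))
    ens <- scan_ensemble(X, mz_grid(300, 301.2, 0.2))
    M <- compute_pcov_map(ens)$matrix
    expect_gt(M[1, 5], 2.5)            # Var(Pois(3)) = 3, most retained
    indep <- M[cbind(c(2, 3, 2), c(3, 4, 6))]
    expect_lt(max(abs(indep)), 0.35)
  })
})

test_that("peak detection finds off-diagonal apexes only", {
  grid <- mz_grid(500, 520, 0.2)
  nb <- length(grid)
  bump <- function(cx, cy) {
    M <- matrix(0, nb, nb)
    for (i in -3:3) for (j in -3:3) {
      M[cx + i, cy + j] <- M[cx + i, cy + j] +
        exp(-(i^2 + j^2) / 2)
      M[cy + j, cx + i] <- M[cx + i, cy + j]
    }
    structure(list(matrix = (M + t(M)) / 2, mz_grid = grid,
                   n_scans = 100,
                   estimator_params = list(estimator = "self")),
              class = "pcov_map")
  }
  zero <- structure(list(matrix = matrix(0, nb, nb), mz_grid = grid,
                         n_scans = 100,
                         estimator_params = list(estimator = "self")),
                    class = "pcov_map")
  expect_equal(nrow(detect_peaks(zero)), 0L)
  pk <- detect_peaks(bump(20, 60), apex_threshold = 0.5)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$bin_x, pk$bin_y), c(20, 60))
  expect_gt(pk$volume, 0)
  # a bump on the diagonal is excluded as autocorrelation
  expect_equal(nrow(detect_peaks(bump(40, 41), apex_threshold = 0.5)), 0L)
  expect_error(detect_peaks(zero, window = 60), "window")
})

test_that("identical scans give zero volume and the Inf score sentinel", {
  ens <- scan_ensemble(matrix(2, 50, 10), mz_grid(100, 102, 0.2))
  expect_warning(
    sc <- jackknife_score(ens, data.frame(bin_x = 2, bin_y = 8),
                          n_groups = 10),
    "Inf")
  expect_equal(sc$volume, 0)
  expect_equal(sc$sigma_jk, 0)
})

test_that("jackknife scores separate a true pair from null coordinates", {
  withr::with_seed(14, {
    grid <- mz_grid(400, 490, 0.2)
    ens <- simulate_scan_ensemble(two_component_model(), 10000, seed = 21)
    true_pair <- data.frame(bin_x = which.min(abs(grid - 410)),
                            bin_y = which.min(abs(grid - 470)))
    nulls <- data.frame(bin_x = sample(5:200, 60, TRUE),
                        bin_y = sample(250:445, 60, TRUE))
    sc <- jackknife_score(ens, rbind(true_pair, nulls))
    true_score <- sc$score[sc$bin_x == true_pair$bin_x &
                             sc$bin_y == true_pair$bin_y]
    expect_gt(true_score, quantile(sc$score[-1], 0.95))
  })
})

test_that("true-pair scores increase with the number of scans", {
  sc_n <- vapply(c(2500, 10000), function(n) {
    grid <- mz_grid(400, 490, 0.2)
    ens <- simulate_scan_ensemble(two_component_model(), n, seed = 22)
    pk <- data.frame(bin_x = which.min(abs(grid - 410)),
                     bin_y = which.min(abs(grid - 470)))
    jackknife_score(ens, pk)$score
  }, numeric(1))
  expect_gt(sc_n[2], sc_n[1])
})

test_that("composite scores accumulate evidence over marker pairs", {
  withr::with_seed(15, {
    grid <- mz_grid(400, 490, 0.2)
    # component A fires two independent coincident pairs
    m <- mixture_model(list(
      list(label = "A", lambda = 50, channels = list(
        fragmentation_channel(data.frame(mz = c(405, 455), yield = 0.5),
                              0.3),
        fragmentation_channel(data.frame(mz = c(415, 465), yield = 0.5),
                              0.3)))),
      grid = grid)
    ens <- simulate_scan_ensemble(m, 5000, seed = 31)
    mk <- data.frame(isomer = c("A", "A", "ghost"),
                     mz_x = c(405, 415, 425),
                     mz_y = c(455, 465, 475))
    comp <- composite_marker_score(ens, mk)
    nearest <- function(z) which.min(abs(grid - z))
    singles <- jackknife_score(
      ens, data.frame(bin_x = vapply(c(405, 415), nearest, integer(1)),
                      bin_y = vapply(c(455, 465), nearest, integer(1))))
    a <- comp[comp$isomer == "A", ]
    expect_equal(a$n_markers, 2L)
    # composite beats the weaker of the two single-marker scores
    expect_gt(a$score, min(singles$score))
    expect_gt(a$score, 5)
    # a coordinate set with no underlying coincidences stays near zero
    expect_lt(abs(comp$score[comp$isomer == "ghost"]), 3)
  })
})

test_that("marker matching is tolerant, nearest-first and tie-broken", {
  # coordinates chosen binary-exact so the two peaks tie precisely
  peaks <- data.frame(bin_x = c(1, 2), bin_y = c(5, 6),
                      mz_x = c(500, 501), mz_y = c(520, 521),
                      apex_height = c(1, 1), volume = c(2, 3),
                      score = c(4, 9))
  mk <- data.frame(isomer = "A", mz_x = 500.5, mz_y = 520.5)
  ev <- match_markers(peaks, mk, tolerance = 0.75, score_threshold = 5)
  # both peaks equidistant: the higher-scoring one wins
  expect_equal(ev$markers$score, 9)
  expect_true(ev$summary$present)
  none <- match_markers(peaks, data.frame(isomer = "B", mz_x = 300,
                                          mz_y = 400))
  expect_false(none$summary$present)
  empty <- match_markers(peaks, data.frame(isomer = character(),
                                           mz_x = numeric(),
                                           mz_y = numeric()))
  expect_equal(nrow(empty$summary), 0L)
  expect_error(match_markers(peaks, mk, tolerance = -1), "positive")
})

test_that("relative quantification normalises marker volumes", {
  ev <- data.frame(isomer = c("A", "B"), volume = c(3, 1))
  q <- relative_quantify(ev)
  expect_equal(q$fraction, c(0.75, 0.25))
  single <- relative_quantify(data.frame(isomer = "A", volume = 2))
  expect_equal(single$fraction, 1)
  expect_error(relative_quantify(data.frame(isomer = "A", volume = 0)),
               "positive")
  expect_error(relative_quantify(data.frame(isomer = c("A", "B"),
                                            volume = c(2, -1))),
               "positive")
})
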