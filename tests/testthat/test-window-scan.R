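test_that("window construction matches the closed-form counts", {
  w <- make_windows(1e6, 1e6, 1e4)
  expect_identical(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(1, 1e6))
  w2 <- make_windows(2e6, 1e6, 1e4)
  expect_identical(nrow(w2), 101L) # floor((L - W)/S) + 1
  expect_true(all(w2$end - w2$start + 1 == 1e6))
  w3 <- make_windows(5.5e6, 1e6, 1e6) # step = window: tiling
  expect_identical(nrow(w3), 5L)
  expect_warning(w4 <- make_windows(5e5, 1e6, 1e4), "whole-chromosome")
  expect_equal(c(w4$start, w4$end), c(1, 5e5))
})

random_track <- function(n = 10000, chrom = "Chr1", length = 5e6, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(length, n))
  tibble::tibble(
    chrom = chrom, pos = pos,
    depth_S = stats::rpois(n, 100) + 1L, depth_R = stats::rpois(n, 100) + 1L,
    index_S = stats::runif(n), index_R = stats::runif(n),
    delta = stats::runif(n, -1, 1)
  )
}

test_that("window means equal a naive per-window loop to 1e-12", {
  tr <- random_track()
  prof <- window_average(tr, window = 1e5, step = 1e5, chrom_lengths = c(Chr1 = 5e6))
  expect_identical(nrow(prof), 50L)
  for (k in seq_len(nrow(prof))) {
    inwin <- tr$pos >= prof$start[k] & tr$pos <= prof$end[k]
    if (!any(inwin)) {
      expect_true(is.na(prof$mean_delta[k]))
    } else {
      expect_lt(abs(prof$mean_delta[k] - mean(tr$delta[inwin])), 1e-12)
      expect_lt(abs(prof$mean_index_S[k] - mean(tr$index_S[inwin])), 1e-12)
      expect_identical(prof$n_sites[k], as.integer(sum(inwin)))
    }
  }
})

test_that("singleton and constant windows behave as identities", {
  tr <- tibble::tibble(
    chrom = "Chr1", pos = c(5e4, 15e4, 25e4),
    depth_S = 100L, depth_R = 100L,
    index_S = 0.5, index_R = 0.2, delta = c(0.1, -0.4, 0.8)
  )
  prof <- window_average(tr, window = 1e5, step = 1e5, chrom_lengths = c(Chr1 = 3e5))
  expect_equal(prof$mean_delta, tr$delta) # one site per window
  trc <- dplyr::mutate(tr, delta = 0.3)
  profc <- window_average(trc, window = 2e5, step = 5e4, chrom_lengths = c(Chr1 = 3e5))
  expect_true(all(profc$mean_delta[!is.na(profc$mean_delta)] == 0.3))
  # empty windows are missing, not zero
  gap <- tr[c(1, 3), ]
  profg <- window_average(gap, window = 1e5, step = 1e5, chrom_lengths = c(Chr1 = 3e5))
  expect_true(is.na(profg$mean_delta[2]))
  expect_identical(profg$n_sites[2], 0L)
})

fake_profile <- function(deltas, chrom = "Chr1", window = 1e5, step = 1e4) {
  n <- length(deltas)
  starts <- 1 + (seq_len(n) - 1) * step
  tibble::tibble(
    chrom = chrom, start = starts, end = starts + window - 1,
    n_sites = 10L, mean_index_S = 0.5, mean_index_R = 0.5,
    mean_delta = deltas, mean_depth_S = 100, mean_depth_R = 100
  )
}

test_that("null profiles yield no regions; a run of hits yields one merged region", {
  ci <- manual_ci(lo = -0.2, hi = 0.2)
  expect_identical(nrow(call_regions(fake_profile(rep(0, 50)), ci, 0.95)), 0L)
  d <- rep(0, 50)
  d[20:25] <- 0.5
  reg <- call_regions(fake_profile(d), ci, 0.95)
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$start, 1 + 19 * 1e4)
  expect_equal(reg$end, 1 + 24 * 1e4 + 1e5 - 1)
  expect_identical(reg$n_windows, 6L)
  expect_identical(reg$direction, 1L)
  expect_equal(reg$peak_delta, 0.5)
  expect_error(call_regions(fake_profile(d), ci, 0.5), "not simulated")
})

test_that("separated runs and opposite signs split regions; order does not matter", {
  ci <- manual_ci(lo = -0.2, hi = 0.2)
  d <- rep(0, 80)
  d[5:8] <- 0.6
  d[40:42] <- -0.6 # far from the first run and opposite in sign
  prof <- fake_profile(d)
  reg <- call_regions(prof, ci, 0.95)
  expect_identical(nrow(reg), 2L)
  expect_identical(sort(reg$direction), c(-1L, 1L))
  # shuffling window rows leaves the calls unchanged
  set.seed(4)
  reg2 <- call_regions(prof[sample.int(nrow(prof)), ], ci, 0.95)
  expect_equal(dplyr::arrange(reg, start), dplyr::arrange(reg2, start))
})

test_that("null band calibration: ~5% of independent single-site windows cross", {
  # one site per non-overlapping window makes the window statistic identical
  # to the per-site statistic the band is built for
  cfg <- null_sim_config(
    bulk_size = 42, replications = 10000,
    depth_grid = 90:110, seed = 777
  )
  ci <- build_ci(cfg)
  map <- sim_genetic_map(5, 20e6, 1e6) # 1 site per Mb
  lens <- stats::setNames(map$chromosomes$length, map$chromosomes$chrom)
  crossed <- 0L
  total <- 0L
  for (s in 1:20) {
    sim <- simulate_bulk_experiment(
      map = map,
      qtl = qtl_spec(chrom = "Chr1", pos = 1e6, additive_effect = 0, noise_sd = 0.15),
      seed = 1000 + s
    )
    tr <- build_delta_track(sim$counts)
    prof <- window_average(tr, window = 1e6, step = 1e6, chrom_lengths = lens)
    prof <- prof[!is.na(prof$mean_delta), ]
    b <- bsaqtl:::band_table(ci, (prof$mean_depth_S + prof$mean_depth_R) / 2, 0.95)
    crossed <- crossed + sum(prof$mean_delta < b$lo | prof$mean_delta > b$hi)
    total <- total + nrow(prof)
  }
  expect_gt(total, 1500)
  expect_lt(abs(crossed / total - 0.05), 0.02)
})

test_that("peak localization error shrinks as effect size grows", {
  map <- sim_genetic_map(2, 20e6, 4e4)
  lens <- stats::setNames(map$chromosomes$length, map$chromosomes$chrom)
  err_for <- function(ratio, seeds) {
    mean(vapply(seeds, function(s) {
      qtl <- qtl_spec(
        chrom = "Chr2", pos = 10e6,
        additive_effect = -0.15 * ratio, noise_sd = 0.15
      )
      sim <- simulate_bulk_experiment(map = map, qtl = qtl, seed = s)
      tr <- build_delta_track(sim$counts)
      prof <- window_average(tr, chrom_lengths = lens)
      pk <- prof[which.max(abs(prof$mean_delta)), ]
      if (pk$chrom != "Chr2") {
        return(25e6) # wrong chromosome: maximal error
      }
      abs((pk$start + pk$end) / 2 - 10e6)
    }, numeric(1)))
  }
  seeds <- 1:6
  e <- c(err_for(0.5, seeds), err_for(1, seeds), err_for(2, seeds))
  expect_true(e[2] <= e[1] && e[3] <= e[2])
})
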