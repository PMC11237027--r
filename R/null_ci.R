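#' Configuration for null-band simulation
#'
#' Describes the no-QTL null model used to build confidence thresholds for
#' the delta SNP-index of an F3 two-bulk design: two bulks of `bulk_size`
#' unselected F3 individuals are drawn per replication, their pool allele
#' frequencies converted to read counts at a fixed depth, and the empirical
#' two-sided quantiles of the resulting delta taken per depth. The defaults
#' follow the study design: 42 individuals per bulk (84 pooled in total),
#' 10,000 replications, an integer depth grid of 80 to 120, and 95%/99%
#' bands.
#'
#' @param bulk_size Individuals per bulk.
#' @param replications Null replications per depth (>= 100).
#' @param depth_grid Sorted positive integer depths.
#' @param levels Confidence levels in (0, 1).
#' @param family_structure `"independent"` draws i.i.d. F3 genotypes at
#'   frequencies (3/8, 1/4, 3/8); `"one_per_family"` draws each F3 through
#'   an explicit F2-then-selfing two-stage scheme (marginally identical,
#'   kept for design fidelity).
#' @param seed Integer master seed; each depth uses its own child stream.
#' @return A `null_sim_config` list.
#' @export
null_sim_config <- function(bulk_size = 42L, replications = 10000L,
                            depth_grid = 80:120, levels = c(0.95, 0.99),
                            family_structure = c("independent", "one_per_family"),
                            seed = 1L) {
  family_structure <- match.arg(family_structure)
  stopifnot(
    bulk_size >= 1L, replications >= 100L,
    length(depth_grid) > 0L, all(depth_grid > 0),
    !is.unsorted(depth_grid),
    all(levels > 0), all(levels < 1)
  )
  structure(
    list(
      bulk_size = as.integer(bulk_size),
      combined_n = 2L * as.integer(bulk_size),
      replications = as.integer(replications),
      depth_grid = as.integer(depth_grid),
      levels = sort(levels),
      family_structure = family_structure,
      seed = as.integer(seed)
    ),
    class = "null_sim_config"
  )
}

#' Draw F3 genotype dosages under the null
#'
#' F3 genotype frequencies at any marker are (3/8, 1/4, 3/8) for dosages
#' (0, 1, 2): selfing an F2 population (1/4, 1/2, 1/4) halves its
#' heterozygosity. Draws come from the current RNG state.
#'
#' @param n Number of individuals.
#' @param family_structure See [null_sim_config()].
#' @return Integer vector of dosages in `{0, 1, 2}`.
#' @export
f3_genotype_draw <- function(n, family_structure = c("independent", "one_per_family")) {
  family_structure <- match.arg(family_structure)
  stopifnot(n >= 1L)
  if (family_structure == "independent") {
    return(sample(0:2, n, replace = TRUE, prob = c(3, 2, 3) / 8))
  }
  f2 <- sample(0:2, n, replace = TRUE, prob = c(1, 2, 1) / 4)
  f3 <- f2
  het <- which(f2 == 1L)
  if (length(het) > 0L) {
    f3[het] <- sample(0:2, length(het), replace = TRUE, prob = c(1, 2, 1) / 4)
  }
  f3
}

#' Simulate null delta SNP-index values at one depth
#'
#' Each replication draws two independent bulks of `cfg$bulk_size` F3
#' dosages, converts each bulk to its pool alternate-allele frequency
#' (mean dosage / 2), samples read counts as Binomial(depth, frequency) per
#' bulk, and records the difference of the two read-level SNP-indices.
#' Binomial read sampling at the pool frequency matches the generator's
#' two-stage per-read member sampling in distribution because pool members
#' are exchangeable.
#'
#' @param cfg A [null_sim_config()].
#' @param depth Reads per site per bulk.
#' @param stream Child-stream label (defaults to one stream per depth, which
#'   is what [build_ci()] uses).
#' @return Numeric vector of length `cfg$replications`.
#' @export
simulate_null_delta <- function(cfg, depth, stream = paste0("null_depth:", depth)) {
  stopifnot(inherits(cfg, "null_sim_config"), depth >= 1)
  reps <- cfg$replications
  with_stream(cfg$seed, stream, {
    f_s <- colMeans(matrix(
      f3_genotype_draw(cfg$bulk_size * reps, cfg$family_structure),
      nrow = cfg$bulk_size
    )) / 2
    f_r <- colMeans(matrix(
      f3_genotype_draw(cfg$bulk_size * reps, cfg$family_structure),
      nrow = cfg$bulk_size
    )) / 2
    idx_s <- stats::rbinom(reps, depth, f_s) / depth
    idx_r <- stats::rbinom(reps, depth, f_r) / depth
    idx_s - idx_r
  })
}

#' Build simulation-based confidence thresholds across a depth grid
#'
#' For every depth in `cfg$depth_grid`, simulates `cfg$replications` null
#' delta SNP-index values and records the two-sided equal-tail empirical
#' quantiles at each confidence level ((1-level)/2 and 1-(1-level)/2). No
#' parametric smoothing is applied. Each depth draws from its own child
#' stream of `cfg$seed`, so bands are reproducible per depth and identical
#' across runs that request different level sets.
#'
#' @param cfg A [null_sim_config()].
#' @return A `ci_thresholds` tibble: `depth`, `level`, `lo`, `hi`, with the
#'   generating configuration attached as attribute `provenance`.
#' @export
build_ci <- function(cfg = null_sim_config()) {
  stopifnot(inherits(cfg, "null_sim_config"))
  for (lv in cfg$levels) {
    if (cfg$replications * (1 - lv) / 2 < 20) {
      warning(
        "fewer than 20 expected exceedances per tail at level ", lv,
        " with ", cfg$replications, " replications"
      )
    }
  }
  rows <- lapply(cfg$depth_grid, function(d) {
    delta <- simulate_null_delta(cfg, d)
    tibble::tibble(
      depth = d,
      level = cfg$levels,
      lo = unname(stats::quantile(delta, (1 - cfg$levels) / 2)),
      hi = unname(stats::quantile(delta, 1 - (1 - cfg$levels) / 2))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- list(
    bulk_size = cfg$bulk_size, combined_n = cfg$combined_n,
    replications = cfg$replications, family_structure = cfg$family_structure,
    depth_grid = range(cfg$depth_grid), levels = cfg$levels, seed = cfg$seed
  )
  class(out) <- c("ci_thresholds", class(out))
  out
}

#' Look up the null band for an observed depth
#'
#' Maps an observed (typically per-window mean) depth onto the simulated
#' grid: the depth is clipped to the grid range, then the nearest grid
#' depth is used, ties going to the lower depth. Clipping is reported via a
#' `clipped` attribute so heavy clipping can be audited.
#'
#' @param ci A `ci_thresholds` from [build_ci()].
#' @param observed_depth Positive depth(s); vectorized.
#' @param level One of the levels the band was built for.
#' @return For scalar input, a named numeric `c(lo, hi)`; for vector input a
#'   tibble `depth_used`, `lo`, `hi`.
#' @export
lookup_band <- function(ci, observed_depth, level = 0.95) {
  stopifnot(inherits(ci, "ci_thresholds"), all(observed_depth > 0))
  levels <- sort(unique(ci$level))
  if (!any(abs(levels - level) < 1e-12)) {
    stop(
      "level ", level, " not simulated; available: ",
      paste(levels, collapse = ", ")
    )
  }
  sub <- ci[abs(ci$level - level) < 1e-12, ]
  grid <- sort(unique(sub$depth))
  x <- pmin(pmax(observed_depth, min(grid)), max(grid))
  clipped <- sum(observed_depth < min(grid) | observed_depth > max(grid))
  # nearest grid depth, ties to the lower one
  pick <- vapply(x, function(xi) {
    d <- abs(grid - xi)
    grid[which.min(d)] # which.min returns the first (= lower) on ties
  }, numeric(1))
  i <- match(pick, sub$depth)
  if (length(observed_depth) == 1L) {
    out <- c(lo = sub$lo[i], hi = sub$hi[i])
  } else {
    out <- tibble::tibble(depth_used = pick, lo = sub$lo[i], hi = sub$hi[i])
  }
  attr(out, "clipped") <- clipped
  out
}
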