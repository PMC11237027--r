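#' Sliding windows over a chromosome
#'
#' Windows are anchored at position 1 and advance by `step`; only full
#' windows fitting within the chromosome are kept (no partial terminal
#' window), unless `keep_partial = TRUE` adds a final truncated window.
#' A window larger than the chromosome degrades to a single
#' whole-chromosome window with a warning.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 1 Mb).
#' @param step Step size in bp (default 10 kb).
#' @param keep_partial Keep a truncated terminal window.
#' @return Tibble `start`, `end` (1-based, inclusive).
#' @export
make_windows <- function(chrom_length, window = 1e6, step = 1e4,
                         keep_partial = FALSE) {
  stopifnot(step > 0, window >= step, chrom_length >= 1)
  if (window > chrom_length) {
    warning("window exceeds chromosome length; using one whole-chromosome window")
    return(tibble::tibble(start = 1, end = chrom_length))
  }
  starts <- seq(1, chrom_length - window + 1, by = step)
  out <- tibble::tibble(start = starts, end = starts + window - 1)
  if (keep_partial && out$end[nrow(out)] < chrom_length) {
    last_start <- out$start[nrow(out)] + step
    if (last_start <= chrom_length) {
      out <- dplyr::bind_rows(
        out,
        tibble::tibble(start = last_start, end = chrom_length)
      )
    }
  }
  out
}

#' Sliding-window means of a delta track
#'
#' Computes the unweighted arithmetic mean of the SNP-indices, delta, and
#' depths over the retained sites falling in each window, per chromosome.
#' Windows containing no site are reported with `n_sites = 0` and `NA`
#' means (missing, not zero).
#'
#' @param track A delta track from [build_delta_track()].
#' @param window,step Window and step size in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   defaults to the last site position per chromosome.
#' @param keep_partial Passed to [make_windows()].
#' @return A window profile tibble: `chrom`, `start`, `end`, `n_sites`,
#'   `mean_index_S`, `mean_index_R`, `mean_delta`, `mean_depth_S`,
#'   `mean_depth_R`.
#' @export
window_average <- function(track, window = 1e6, step = 1e4,
                           chrom_lengths = NULL, keep_partial = FALSE) {
  stopifnot(all(c("chrom", "pos", "delta") %in% names(track)))
  chroms <- unique(track$chrom)
  profiles <- lapply(chroms, function(ch) {
    tr <- track[track$chrom == ch, ]
    tr <- tr[order(tr$pos), ]
    len <- if (!is.null(chrom_lengths)) {
      if (!(ch %in% names(chrom_lengths))) {
        stop("no chromosome length for ", ch)
      }
      chrom_lengths[[ch]]
    } else {
      max(tr$pos)
    }
    win <- make_windows(len, window, step, keep_partial)
    nw <- nrow(win)
    # first/last site index per window on the sorted position vector
    i1 <- findInterval(win$start - 1, tr$pos) + 1L
    i2 <- findInterval(win$end, tr$pos)
    wmean <- function(x) {
      vapply(seq_len(nw), function(k) {
        if (i2[k] < i1[k]) NA_real_ else mean(x[i1[k]:i2[k]])
      }, numeric(1))
    }
    tibble::tibble(
      chrom = ch,
      start = win$start,
      end = win$end,
      n_sites = pmax(i2 - i1 + 1L, 0L),
      mean_index_S = wmean(tr$index_S),
      mean_index_R = wmean(tr$index_R),
      mean_delta = wmean(tr$delta),
      mean_depth_S = wmean(as.numeric(tr$depth_S)),
      mean_depth_R = wmean(as.numeric(tr$depth_R))
    )
  })
  dplyr::bind_rows(profiles)
}

#' Call candidate QTL regions against null confidence bands
#'
#' Flags windows whose mean delta SNP-index falls outside the two-sided
#' null band for the window's depth (mean of the two pools' mean depths,
#' looked up on the simulated grid via [lookup_band()]), then merges
#' overlapping or adjacent significant windows of the same sign into
#' regions. Because consecutive windows overlap by `window - step`,
#' a run of significant windows merges into one region; a gap of at least
#' one full window of non-significance separates regions.
#'
#' @param profile A window profile from [window_average()].
#' @param ci A `ci_thresholds` from [build_ci()].
#' @param level Confidence level to call at (must be simulated).
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_delta` (signed extreme window mean), `peak_start`, `peak_end`,
#'   `direction` (+1/-1), `level`. Zero rows when nothing crosses.
#' @export
call_regions <- function(profile, ci, level = 0.95) {
  stopifnot(all(c("chrom", "start", "end", "mean_delta") %in% names(profile)))
  ok <- !is.na(profile$mean_delta)
  prof <- profile[ok, ]
  if (nrow(prof) == 0L) {
    return(empty_regions(level))
  }
  depth_obs <- (prof$mean_depth_S + prof$mean_depth_R) / 2
  band <- band_table(ci, depth_obs, level)
  sig_hi <- prof$mean_delta > band$hi
  sig_lo <- prof$mean_delta < band$lo
  sig <- sig_hi | sig_lo
  if (!any(sig)) {
    return(empty_regions(level))
  }
  hits <- prof[sig, ]
  hits$direction <- ifelse(sig_hi[sig], 1L, -1L)
  regions <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, ]
    h <- h[order(h$start), ]
    run_start <- 1L
    for (k in seq_len(nrow(h))) {
      closes <- k == nrow(h) ||
        h$start[k + 1L] > h$end[k] + 1 ||
        h$direction[k + 1L] != h$direction[k]
      if (closes) {
        run <- h[run_start:k, ]
        peak <- which.max(abs(run$mean_delta))
        regions[[length(regions) + 1L]] <- tibble::tibble(
          chrom = ch,
          start = min(run$start),
          end = max(run$end),
          n_windows = nrow(run),
          peak_delta = run$mean_delta[peak],
          peak_start = run$start[peak],
          peak_end = run$end[peak],
          direction = run$direction[1L],
          level = level
        )
        run_start <- k + 1L
      }
    }
  }
  dplyr::bind_rows(regions)
}

# lookup_band as a tibble regardless of input length
band_table <- function(ci, depth_obs, level) {
  b <- lookup_band(ci, depth_obs, level = level)
  if (!is.data.frame(b)) {
    b <- tibble::tibble(depth_used = NA_real_, lo = b[["lo"]], hi = b[["hi"]])
  }
  b
}

empty_regions <- function(level) {
  tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    n_windows = integer(), peak_delta = numeric(),
    peak_start = numeric(), peak_end = numeric(),
    direction = integer(), level = numeric()
  )
}

#' Plot a delta SNP-index window profile with its null bands
#'
#' @param profile A window profile from [window_average()].
#' @param ci A `ci_thresholds`.
#' @param levels Confidence levels to draw.
#' @return A ggplot object: mean delta per window midpoint, faceted by
#'   chromosome, with dashed band lines per level.
#' @export
plot_delta_profile <- function(profile, ci, levels = c(0.95, 0.99)) {
  prof <- profile[!is.na(profile$mean_delta), ]
  prof$mid <- (prof$start + prof$end) / 2
  depth_obs <- (prof$mean_depth_S + prof$mean_depth_R) / 2
  bands <- dplyr::bind_rows(lapply(levels, function(lv) {
    b <- band_table(ci, depth_obs, lv)
    tibble::tibble(
      chrom = prof$chrom, mid = prof$mid,
      lo = b$lo, hi = b$hi, level = factor(lv)
    )
  }))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$mid / 1e6)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_delta), colour = "red") +
    ggplot2::geom_line(
      data = bands,
      ggplot2::aes(y = .data$lo, linetype = .data$level), colour = "grey30"
    ) +
    ggplot2::geom_line(
      data = bands,
      ggplot2::aes(y = .data$hi, linetype = .data$level), colour = "grey30"
    ) +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(
      x = "position (Mb)", y = expression(Delta * " SNP-index"),
      linetype = "CI level"
    ) +
    ggplot2::theme_minimal()
}
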