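# Shared fixtures built in code: tiny maps, parents, and hand-made bands.

# A map with one 2-marker chromosome per requested genetic distance (cM).
pairs_map <- function(d_cM, phys_per_cM = 1e5) {
  markers <- dplyr::bind_rows(lapply(seq_along(d_cM), function(i) {
    tibble::tibble(
      chrom = paste0("Chr", i),
      pos = c(1e5, 1e5 + max(d_cM[i], 1e-9) * phys_per_cM),
      cM = c(0, d_cM[i])
    )
  }))
  lens <- stats::setNames(
    rep(max(markers$pos) + 1e5, length(d_cM)),
    paste0("Chr", seq_along(d_cM))
  )
  genetic_map(markers, lens)
}

# Fully heterozygous (F1-style) phased parent for a map.
f1_parent <- function(map) {
  m <- nrow(map$markers)
  list(hap1 = rep(0L, m), hap2 = rep(1L, m))
}

# Hand-made confidence thresholds (symmetric unless stated otherwise).
manual_ci <- function(depth = 100L, lo = -0.2, hi = 0.2, level = 0.95) {
  ci <- tibble::tibble(depth = depth, level = level, lo = lo, hi = hi)
  class(ci) <- c("ci_thresholds", class(ci))
  ci
}

# Random weight table with a reference line and n other lines.
random_weights <- function(n = 5, reference = "Col-0", seed = 1) {
  set.seed(seed)
  ids <- c(reference, sprintf("L%02d", seq_len(n)))
  tibble::tibble(
    line_id = rep(ids, each = 6),
    condition = rep(rep(c("TM", "DMSO"), each = 3), length(ids)),
    replicate = rep(1:3, 2 * length(ids)),
    weight_mg = stats::runif(6 * length(ids), 1, 50)
  )
}

# Swap the S and R pools of an allele-count table.
swap_pools <- function(counts) {
  dplyr::rename(counts,
    ref_count_S = "ref_count_R", alt_count_S = "alt_count_R",
    ref_count_R = "ref_count_S", alt_count_R = "alt_count_S"
  )
}
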