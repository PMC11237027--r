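#' Per-site SNP-index
#'
#' The SNP-index of a pool at a site is the fraction of its reads carrying
#' the non-reference (alternate) allele: `alt / (ref + alt)`.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized).
#' @return Numeric vector in `[0, 1]`. Zero-depth sites are an error: they
#'   must be excluded upstream rather than propagated as NaN.
#' @export
#' @examples
#' site_snp_index(6, 2) # 0.25
site_snp_index <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0)) stop("negative read count")
  depth <- ref_count + alt_count
  if (any(depth == 0)) {
    stop("zero-depth site(s): exclude them before computing SNP-indices")
  }
  alt_count / depth
}

#' Site filter configuration
#'
#' @param min_depth Minimum read depth required in *each* pool. Low-depth
#'   sites carry noisy indices that dominate window variance, so a floor of
#'   10 reads per pool is applied by default.
#' @param min_total_index Optional floor on the combined SNP-index
#'   `(alt_S + alt_R) / (depth_S + depth_R)`, to drop monomorphic-reference
#'   artifacts. Off (0) by default.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10L, min_total_index = 0) {
  stopifnot(min_depth >= 0, min_total_index >= 0, min_total_index < 1)
  structure(
    list(min_depth = min_depth, min_total_index = min_total_index),
    class = "filter_config"
  )
}

#' Per-site SNP-index and delta SNP-index track from two-bulk counts
#'
#' Computes the SNP-index of the hyper-sensitive (S) and hyper-resistant
#' (R) pools at every retained site and their difference
#' `delta = index_S - index_R`. Under the no-QTL null, delta fluctuates
#' around 0; near a QTL linked to the selected trait the two bulks are
#' enriched for opposite parental alleles and delta deviates towards
#' +/- 1. Sites failing the depth or combined-index filters are removed;
#' filtering is idempotent and its funnel is recorded in the
#' `filter_summary` attribute.
#'
#' @param counts Allele-count table: `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count_S`, `alt_count_S`, `ref_count_R`, `alt_count_R`, unique and
#'   sorted by `(chrom, pos)`.
#' @param filters A [filter_config()].
#' @return Tibble `chrom`, `pos`, `depth_S`, `depth_R`, `index_S`,
#'   `index_R`, `delta`, sorted by `(chrom, pos)`, with attribute
#'   `filter_summary`.
#' @export
build_delta_track <- function(counts, filters = filter_config()) {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0L) stop("empty allele-count table")
  depth_s <- counts$ref_count_S + counts$alt_count_S
  depth_r <- counts$ref_count_R + counts$alt_count_R
  keep_depth <- depth_s >= filters$min_depth & depth_r >= filters$min_depth
  tot <- depth_s + depth_r
  comb <- ifelse(tot > 0, (counts$alt_count_S + counts$alt_count_R) / tot, 0)
  keep_index <- comb >= filters$min_total_index
  keep <- keep_depth & keep_index
  summary <- list(
    n_input = nrow(counts),
    n_removed_depth = sum(!keep_depth),
    n_removed_index = sum(keep_depth & !keep_index),
    n_retained = sum(keep),
    min_depth = filters$min_depth,
    min_total_index = filters$min_total_index
  )
  if (summary$n_retained == 0L) {
    stop(
      "all ", summary$n_input, " sites filtered out (",
      summary$n_removed_depth, " below depth ", filters$min_depth, ", ",
      summary$n_removed_index, " below combined index ",
      filters$min_total_index, ")"
    )
  }
  idx_s <- counts$alt_count_S[keep] / depth_s[keep]
  idx_r <- counts$alt_count_R[keep] / depth_r[keep]
  out <- tibble::tibble(
    chrom = counts$chrom[keep],
    pos = counts$pos[keep],
    depth_S = as.integer(depth_s[keep]),
    depth_R = as.integer(depth_r[keep]),
    index_S = idx_s,
    index_R = idx_r,
    delta = idx_s - idx_r
  )
  attr(out, "filter_summary") <- summary
  out
}

# Common validation for allele-count tables: required columns, non-negative
# counts, unique sorted sites (sorts with a warning if needed).
validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c(
    "chrom", "pos", "ref", "alt",
    "ref_count_S", "alt_count_S", "ref_count_R", "alt_count_R"
  )
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0L) {
    stop("allele-count table lacks column(s): ", paste(miss, collapse = ", "))
  }
  cnt <- c(
    counts$ref_count_S, counts$alt_count_S,
    counts$ref_count_R, counts$alt_count_R
  )
  if (any(is.na(cnt)) || any(cnt < 0)) stop("counts must be non-negative")
  key <- paste(counts$chrom, counts$pos)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos) site(s)")
  ord <- order(counts$chrom, counts$pos)
  if (!identical(ord, seq_len(nrow(counts)))) {
    warning("allele-count table was unsorted; sorting by (chrom, pos)")
    counts <- counts[ord, ]
  }
  counts
}
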