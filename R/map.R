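#' Construct a genetic map
#'
#' A genetic map ties physical marker positions (base pairs) to genetic
#' positions (centiMorgans) on one or more chromosomes. It drives the meiosis
#' simulator: crossover locations are uniform in genetic distance, so the
#' bp-to-cM relation encodes local recombination rate.
#'
#' @param markers Data frame with columns `chrom` (character), `pos`
#'   (1-based bp, strictly increasing within a chromosome), `cM`
#'   (non-decreasing within a chromosome), and optionally `ref` and `alt`
#'   (single bases; filled in if absent).
#' @param chrom_lengths Named numeric vector of physical chromosome lengths
#'   in bp; names must cover every chromosome in `markers`.
#' @return An object of class `genetic_map`: a list with elements
#'   `chromosomes` (tibble: `chrom`, `length`) and `markers` (tibble:
#'   `chrom`, `pos`, `cM`, `ref`, `alt`).
#' @export
genetic_map <- function(markers, chrom_lengths) {
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("chrom", "pos", "cM") %in% names(markers)))
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("`chrom_lengths` must be a named vector of chromosome lengths")
  }
  chroms <- unique(markers$chrom)
  missing <- setdiff(chroms, names(chrom_lengths))
  if (length(missing) > 0L) {
    stop("no length given for chromosome(s): ", paste(missing, collapse = ", "))
  }
  markers <- dplyr::arrange(markers, .data$chrom, .data$pos)
  for (ch in chroms) {
    mk <- markers[markers$chrom == ch, ]
    if (nrow(mk) < 2L) {
      stop("chromosome ", ch, " has fewer than 2 markers")
    }
    if (any(diff(mk$pos) <= 0)) {
      stop("marker positions must be strictly increasing on chromosome ", ch)
    }
    if (any(diff(mk$cM) < 0)) {
      stop("genetic positions must be non-decreasing on chromosome ", ch)
    }
    if (mk$pos[1L] < 1 || mk$pos[nrow(mk)] > chrom_lengths[[ch]]) {
      stop("marker positions outside [1, length] on chromosome ", ch)
    }
  }
  if (!("ref" %in% names(markers)) || !("alt" %in% names(markers))) {
    # deterministic dummy alleles; real data carries its own
    bases <- c("A", "C", "G", "T")
    i <- (seq_len(nrow(markers)) - 1L) %% 4L
    markers$ref <- bases[i + 1L]
    markers$alt <- bases[(i + 1L) %% 4L + 1L]
  }
  structure(
    list(
      chromosomes = tibble::tibble(
        chrom = chroms,
        length = as.numeric(chrom_lengths[chroms])
      ),
      markers = markers
    ),
    class = "genetic_map"
  )
}

#' Build a regular synthetic genetic map
#'
#' Convenience constructor for the synthetic-data generator: `n_chrom`
#' chromosomes of equal physical length with markers every `marker_spacing`
#' bp and a uniform recombination rate (`cM_per_Mb`). Defaults emulate an
#' Arabidopsis-scale genome at desk scale: 5 chromosomes of 20 Mb with a
#' 10 kb marker grid and 4 cM/Mb.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Physical length of each chromosome in bp.
#' @param marker_spacing Distance between adjacent markers in bp.
#' @param cM_per_Mb Uniform recombination rate.
#' @return A `genetic_map`.
#' @export
sim_genetic_map <- function(n_chrom = 5L, chrom_length = 20e6,
                            marker_spacing = 1e4, cM_per_Mb = 4) {
  pos1 <- seq(marker_spacing, chrom_length, by = marker_spacing)
  markers <- tibble::tibble(
    chrom = rep(paste0("Chr", seq_len(n_chrom)), each = length(pos1)),
    pos = rep(pos1, n_chrom),
    cM = rep(pos1 * cM_per_Mb / 1e6, n_chrom)
  )
  lens <- stats::setNames(rep(chrom_length, n_chrom), paste0("Chr", seq_len(n_chrom)))
  genetic_map(markers, lens)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(
    "<genetic_map>", nrow(x$chromosomes), "chromosome(s),",
    nrow(x$markers), "markers\n"
  )
  invisible(x)
}

n_markers <- function(map) nrow(map$markers)
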