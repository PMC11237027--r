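#' Relative-response ratio from treated/control fresh weights
#'
#' For every line, the ratio of its fresh weight under treatment to its
#' fresh weight under the control is divided by the same ratio for the
#' reference line:
#' `RR = [line (G_trt / G_ctl)] / [reference (G_trt / G_ctl)]`.
#' The reference therefore has RR = 1 by construction, lines more sensitive
#' than the reference fall below 1, and more resistant lines rise above 1.
#' RR is scale-free: rescaling every weight by a constant leaves it
#' unchanged.
#'
#' Replicates are combined per condition by their arithmetic mean before the
#' ratio is taken (`mode = "condition_means"`, the default). Alternatively
#' (`mode = "per_replicate"`) treated/control ratios are formed within each
#' replicate index first and then averaged.
#'
#' @param weights Data frame with columns `line_id`, `condition`,
#'   `replicate`, `weight_mg`; all weights must be positive.
#' @param reference Line id of the reference (denominator) accession.
#' @param treatment,control Condition labels.
#' @param mode Replicate aggregation, see Details.
#' @return Tibble with `line_id`, `ratio` (treated/control) and `rr`; the
#'   reference row has `rr == 1` exactly.
#' @export
#' @examples
#' w <- data.frame(
#'   line_id = rep(c("Col-0", "L1"), each = 2),
#'   condition = rep(c("TM", "DMSO"), 2),
#'   replicate = 1L,
#'   weight_mg = c(3, 6, 2, 8)
#' )
#' compute_rr(w, reference = "Col-0")
compute_rr <- function(weights, reference = "Col-0",
                       treatment = "TM", control = "DMSO",
                       mode = c("condition_means", "per_replicate")) {
  mode <- match.arg(mode)
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("line_id", "condition", "weight_mg") %in% names(weights)))
  if (any(weights$weight_mg <= 0)) stop("all weights must be positive")
  keep <- weights$condition %in% c(treatment, control)
  weights <- weights[keep, ]
  if (!(reference %in% weights$line_id)) {
    stop("reference line ", reference, " absent from the weight table")
  }
  if (mode == "condition_means") {
    agg <- weights |>
      dplyr::summarise(
        m = mean(.data$weight_mg),
        .by = c("line_id", "condition")
      ) |>
      spread_conditions(treatment, control)
    ratio <- agg$trt / agg$ctl
    out <- tibble::tibble(line_id = agg$line_id, ratio = ratio)
  } else {
    if (!("replicate" %in% names(weights))) {
      stop("per_replicate mode needs a `replicate` column")
    }
    wide <- weights |>
      dplyr::summarise(
        m = mean(.data$weight_mg),
        .by = c("line_id", "replicate", "condition")
      ) |>
      spread_conditions(treatment, control, by_rep = TRUE)
    out <- wide |>
      dplyr::summarise(
        ratio = mean(.data$trt / .data$ctl),
        .by = "line_id"
      )
  }
  dropped <- out$line_id[!is.finite(out$ratio)]
  complete <- is.finite(out$ratio)
  if (reference %in% dropped) {
    stop("reference line ", reference, " lacks a condition")
  }
  if (length(dropped) > 0L) {
    warning(
      length(dropped), " line(s) dropped for missing a condition: ",
      paste(utils::head(dropped, 5L), collapse = ", ")
    )
    out <- out[complete, ]
  }
  ref_ratio <- out$ratio[out$line_id == reference]
  out$rr <- out$ratio / ref_ratio
  out$rr[out$line_id == reference] <- 1 # exact, not up to rounding
  out
}

# minimal wide-spread of condition means without depending on tidyr
spread_conditions <- function(df, treatment, control, by_rep = FALSE) {
  keys <- if (by_rep) c("line_id", "replicate") else "line_id"
  trt <- df[df$condition == treatment, c(keys, "m")]
  ctl <- df[df$condition == control, c(keys, "m")]
  names(trt)[names(trt) == "m"] <- "trt"
  names(ctl)[names(ctl) == "m"] <- "ctl"
  dplyr::full_join(trt, ctl, by = keys)
}

#' Select extreme phenotypic tails into bulks
#'
#' Lines are ranked by their relative-response value; the lowest tail forms
#' the hyper-sensitive bulk and the highest tail the hyper-resistant bulk.
#' Both tails are taken from a single stable ordering by `(rr, line_id)`, so
#' ties at a tail boundary are broken deterministically by line id and the
#' two bulks are always disjoint. Membership depends only on ranks, so any
#' strictly monotone transform of the values leaves it unchanged.
#'
#' @param rr Data frame with columns `line_id` and `rr`.
#' @param tail_fraction Fraction of lines per tail, in (0, 0.5).
#' @param tail_count Optional explicit bulk size overriding
#'   `tail_fraction` (the study pooled 42 individuals per 10% tail of 400).
#' @return List with character vectors `sensitive` and `resistant` (line
#'   ids, each sorted in selection order).
#' @export
select_tails <- function(rr, tail_fraction = 0.1, tail_count = NULL) {
  rr <- tibble::as_tibble(rr)
  stopifnot(all(c("line_id", "rr") %in% names(rr)))
  rr <- rr[!is.na(rr$rr), ]
  n <- nrow(rr)
  if (!is.null(tail_count)) {
    size <- as.integer(tail_count)
  } else {
    if (tail_fraction <= 0 || tail_fraction >= 0.5) {
      stop("tail_fraction must be in (0, 0.5)")
    }
    size <- as.integer(round(n * tail_fraction))
  }
  if (size < 1L) stop("tail size is zero")
  if (2L * size > n) stop("tails of ", size, " would overlap in ", n, " lines")
  ord <- order(rr$rr, rr$line_id)
  list(
    sensitive = rr$line_id[ord[seq_len(size)]],
    resistant = rr$line_id[ord[seq.int(n - size + 1L, n)]]
  )
}
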