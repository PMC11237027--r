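#' @importFrom rlang .data
NULL

# Batched meiosis under Haldane's model (Poisson crossovers, no
# interference, uniform in genetic distance).
#
# hap_a, hap_b: integer matrices (individuals x markers) holding the two
# phased haplotypes of every potential parent; parent: integer vector giving
# the parent row for each requested gamete. Returns a (gametes x markers)
# integer matrix. Crossovers are drawn on the genetic span covered by the
# markers of each chromosome; crossovers outside that span cannot change a
# genotype and are not modelled.
meiosis_batch <- function(hap_a, hap_b, parent, map) {
  g <- length(parent)
  m <- n_markers(map)
  gam <- matrix(0L, nrow = g, ncol = m)
  mk <- map$markers
  for (ch in map$chromosomes$chrom) {
    idx <- which(mk$chrom == ch)
    cm <- mk$cM[idx]
    span <- cm[length(cm)] - cm[1L]
    n_cx <- stats::rpois(g, span / 100) # genetic length in Morgans
    total <- sum(n_cx)
    if (total > 0L) {
      cx_pos <- stats::runif(total, min = cm[1L], max = cm[length(cm)])
      cx_gid <- rep.int(seq_len(g), n_cx)
      o <- order(cx_pos)
      cx_pos <- cx_pos[o]
      cx_gid <- cx_gid[o]
    } else {
      cx_pos <- numeric(0)
      cx_gid <- integer(0)
    }
    # which of the two parental haplotypes each gamete starts on
    parity <- sample(0:1, g, replace = TRUE)
    cnt <- integer(g)
    ptr <- 1L
    for (j in seq_along(idx)) {
      while (ptr <= total && cx_pos[ptr] < cm[j]) {
        gid <- cx_gid[ptr]
        cnt[gid] <- cnt[gid] + 1L
        ptr <- ptr + 1L
      }
      ph <- (parity + cnt) %% 2L
      col <- idx[j]
      a <- hap_a[cbind(parent, col)]
      b <- hap_b[cbind(parent, col)]
      gam[, col] <- a + (b - a) * ph
    }
  }
  gam
}

#' Simulate one gamete from a phased diploid parent
#'
#' Meiosis follows Haldane's model: the number of crossovers per chromosome
#' is Poisson with mean equal to the chromosome's genetic length in Morgans,
#' crossover locations are uniform in genetic distance, and there is no
#' interference. The returned gamete is a mosaic of the parent's two
#' haplotypes.
#'
#' @param parent A list with elements `hap1` and `hap2`, integer vectors of
#'   per-marker alleles in `{0, 1}` ordered as `map$markers`. Phase is
#'   required; passing a single dosage vector is an error because meiosis is
#'   undefined without it.
#' @param map A [genetic_map()].
#' @return Integer vector of per-marker alleles in `{0, 1}`.
#' @export
simulate_gamete <- function(parent, map) {
  if (!is.list(parent) || !all(c("hap1", "hap2") %in% names(parent))) {
    stop(
      "parent must be a phased diploid: list(hap1=, hap2=); ",
      "dosages alone cannot be segregated through meiosis"
    )
  }
  m <- n_markers(map)
  stopifnot(length(parent$hap1) == m, length(parent$hap2) == m)
  hap_a <- matrix(as.integer(parent$hap1), nrow = 1L)
  hap_b <- matrix(as.integer(parent$hap2), nrow = 1L)
  drop(meiosis_batch(hap_a, hap_b, 1L, map))
}

#' Simulate an F2 or F3 population from a biparental cross
#'
#' Two fully homozygous inbred parents (all-reference and all-alternate
#' haplotypes) are crossed to give an F1 (heterozygous everywhere). The F1
#' is selfed to produce `n_f2` F2 individuals; each F3 individual is
#' produced by selfing one F2 parent (two independent gametes). By default
#' one F3 is taken per F2 family, matching a 400 F2 -> 400 F3 design; F3
#' individuals are assigned to F2 families round-robin when
#' `progeny_per_family > 1`.
#'
#' @param n_f2 Number of F2 individuals.
#' @param n_f3 Number of F3 individuals (ignored when `generation = "F2"`).
#' @param map A [genetic_map()].
#' @param seed Integer master seed; meiosis draws come from named child
#'   streams (`"f2"`, `"f3"`) of this seed.
#' @param generation `"F3"` (default) or `"F2"`.
#' @param progeny_per_family Maximum F3 progeny per F2 family.
#' @return A `diploid_population`: list with `hap_a`/`hap_b` (individuals x
#'   markers integer matrices), `id`, `family`, `generation`, and `map`.
#' @export
make_population <- function(n_f2, n_f3 = n_f2, map, seed,
                            generation = c("F3", "F2"),
                            progeny_per_family = 1L) {
  generation <- match.arg(generation)
  if (n_f2 < 1L) stop("n_f2 must be at least 1")
  m <- n_markers(map)
  # F1: one all-ref and one all-alt haplotype at every marker
  f1_a <- matrix(0L, nrow = 1L, ncol = m)
  f1_b <- matrix(1L, nrow = 1L, ncol = m)
  f2_gam <- with_stream(seed, "f2", {
    meiosis_batch(f1_a, f1_b, rep(1L, 2L * n_f2), map)
  })
  f2_a <- f2_gam[seq_len(n_f2), , drop = FALSE]
  f2_b <- f2_gam[n_f2 + seq_len(n_f2), , drop = FALSE]
  if (generation == "F2") {
    return(new_population(f2_a, f2_b,
      id = sprintf("F2_%04d", seq_len(n_f2)),
      family = seq_len(n_f2), generation = "F2", map = map
    ))
  }
  if (n_f3 > n_f2 * progeny_per_family) {
    stop("n_f3 exceeds n_f2 * progeny_per_family")
  }
  fam <- ((seq_len(n_f3) - 1L) %% n_f2) + 1L
  f3_gam <- with_stream(seed, "f3", {
    meiosis_batch(f2_a, f2_b, c(fam, fam), map)
  })
  new_population(
    f3_gam[seq_len(n_f3), , drop = FALSE],
    f3_gam[n_f3 + seq_len(n_f3), , drop = FALSE],
    id = sprintf("F3_%04d", seq_len(n_f3)),
    family = fam, generation = "F3", map = map
  )
}

new_population <- function(hap_a, hap_b, id, family, generation, map) {
  structure(
    list(
      hap_a = hap_a, hap_b = hap_b, id = id,
      family = family, generation = generation, map = map
    ),
    class = "diploid_population"
  )
}

#' @export
print.diploid_population <- function(x, ...) {
  cat(
    "<diploid_population>", length(x$id), x$generation, "individuals,",
    ncol(x$hap_a), "markers\n"
  )
  invisible(x)
}

#' Alt-allele dosage matrix of a population
#'
#' @param pop A `diploid_population`.
#' @return Integer matrix (individuals x markers) with entries in `{0,1,2}`
#'   counting copies of the alternate (second-parent) allele.
#' @export
dosage <- function(pop) {
  stopifnot(inherits(pop, "diploid_population"))
  pop$hap_a + pop$hap_b
}

#' Specify the planted QTL and trait model
#'
#' The simulated trait is
#' `baseline + additive_effect * (dosage - 1) + dominance_effect * [dosage == 1]
#'  + Normal(0, noise_sd)`,
#' where dosage counts alternate-parent alleles at the marker nearest (at or
#' left of) the QTL position. Defaults plant a single major locus near the
#' end of Chr2 on a relative-response scale: a heterozygote baseline of
#' 0.85 with -0.3 per alternate allele spans roughly 0.55-1.15 across
#' genotypes, with residual noise 0.15 (the additive effect is twice the
#' noise SD, a strong single QTL), so that alternate-allele carriers are the
#' stress-sensitive extreme.
#'
#' @param chrom Chromosome carrying the QTL.
#' @param pos QTL position in bp.
#' @param additive_effect Trait units per alternate-allele copy.
#' @param dominance_effect Trait units added to heterozygotes.
#' @param noise_sd Residual SD in trait units (>= 0).
#' @param baseline Trait value of a heterozygote with no dominance.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chrom = "Chr2", pos = 18.5e6, additive_effect = -0.3,
                     dominance_effect = 0, noise_sd = 0.15, baseline = 0.85) {
  stopifnot(noise_sd >= 0, pos >= 1)
  structure(
    list(
      chrom = chrom, pos = pos, additive_effect = additive_effect,
      dominance_effect = dominance_effect, noise_sd = noise_sd,
      baseline = baseline
    ),
    class = "qtl_spec"
  )
}

# Index of the marker at or immediately left of the QTL position.
qtl_marker_index <- function(map, qtl) {
  mk <- map$markers
  on_chr <- which(mk$chrom == qtl$chrom)
  if (length(on_chr) == 0L) {
    stop("QTL chromosome ", qtl$chrom, " is not on the map")
  }
  left <- on_chr[mk$pos[on_chr] <= qtl$pos]
  if (length(left) == 0L) {
    warning("no marker at or left of the QTL position; using the first marker")
    return(on_chr[1L])
  }
  left[length(left)]
}

#' Assign phenotypes from the planted QTL
#'
#' @param pop A `diploid_population`.
#' @param qtl A [qtl_spec()].
#' @param seed Integer master seed (child stream `"phenotype"`).
#' @return Tibble with `id`, `family`, `qtl_dosage`, `phenotype`; the marker
#'   used for the QTL is recorded in attribute `qtl_marker`.
#' @export
assign_phenotypes <- function(pop, qtl, seed) {
  stopifnot(inherits(pop, "diploid_population"), inherits(qtl, "qtl_spec"))
  j <- qtl_marker_index(pop$map, qtl)
  d <- dosage(pop)[, j]
  n <- length(d)
  noise <- with_stream(seed, "phenotype", stats::rnorm(n, 0, qtl$noise_sd))
  ph <- qtl$baseline + qtl$additive_effect * (d - 1) +
    qtl$dominance_effect * as.numeric(d == 1L) + noise
  out <- tibble::tibble(
    id = pop$id, family = pop$family, qtl_dosage = d, phenotype = ph
  )
  attr(out, "qtl_marker") <- pop$map$markers[j, c("chrom", "pos")]
  out
}

#' Pooled-sequencing configuration
#'
#' @param mean_depth Mean reads per site per pool.
#' @param depth_distribution `"poisson"` (default) or `"fixed"`.
#' @param error_rate Per-read probability of flipping the observed allele,
#'   in `[0, 0.5)`.
#' @return A `poolseq_config` list.
#' @export
poolseq_config <- function(mean_depth = 100, depth_distribution = c("poisson", "fixed"),
                           error_rate = 0) {
  depth_distribution <- match.arg(depth_distribution)
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  structure(
    list(
      mean_depth = mean_depth, depth_distribution = depth_distribution,
      error_rate = error_rate
    ),
    class = "poolseq_config"
  )
}

#' Sequence a DNA pool of selected individuals
#'
#' Reads are sampled in two stages: for every read, a pool member is chosen
#' uniformly at random, then an allele is drawn with probability dosage/2
#' for the alternate allele, and finally flipped with probability
#' `error_rate`. The two-stage scheme represents the finite composition of
#' the bulk exactly; because members are chosen independently per read it
#' coincides in distribution with binomial sampling at the pool allele
#' frequency.
#'
#' @param pop A `diploid_population`.
#' @param member_ids Ids of pooled individuals (must be present in `pop`).
#' @param sites Optional data frame of `chrom`, `pos` to restrict to; `NULL`
#'   means all map markers.
#' @param cfg A [poolseq_config()].
#' @param seed Integer master seed.
#' @param stream Child-stream label, so the two bulks of one experiment draw
#'   independently.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`
#'   with `ref_count + alt_count` equal to the drawn depth at every site.
#' @export
pool_and_sequence <- function(pop, member_ids, sites = NULL, cfg = poolseq_config(),
                              seed, stream = "poolseq") {
  stopifnot(inherits(pop, "diploid_population"), inherits(cfg, "poolseq_config"))
  if (length(member_ids) == 0L) stop("member_ids is empty")
  rows <- match(member_ids, pop$id)
  if (anyNA(rows)) {
    stop("member id(s) not in population: ", paste(member_ids[is.na(rows)][1:5], collapse = ", "))
  }
  mk <- pop$map$markers
  if (is.null(sites)) {
    site_idx <- seq_len(nrow(mk))
  } else {
    site_idx <- match(
      paste(sites$chrom, sites$pos),
      paste(mk$chrom, mk$pos)
    )
    if (anyNA(site_idx)) stop("requested site(s) not on the map")
  }
  dos <- dosage(pop)[rows, , drop = FALSE]
  n_mem <- length(rows)
  n_site <- length(site_idx)
  with_stream(seed, stream, {
    depth <- switch(cfg$depth_distribution,
      poisson = stats::rpois(n_site, cfg$mean_depth),
      fixed = rep.int(as.integer(round(cfg$mean_depth)), n_site)
    )
    total <- sum(depth)
    site_of_read <- rep.int(seq_len(n_site), depth)
    mem <- sample.int(n_mem, total, replace = TRUE)
    d <- dos[cbind(mem, site_idx[site_of_read])]
    alt <- stats::rbinom(total, 1L, d / 2)
    if (cfg$error_rate > 0) {
      flip <- stats::rbinom(total, 1L, cfg$error_rate)
      alt <- as.integer(xor(alt == 1L, flip == 1L))
    }
    alt_count <- as.integer(rowsum(alt, site_of_read, reorder = TRUE))
    # rowsum drops empty groups; rebuild against the full site list
    if (any(depth == 0L)) {
      full <- integer(n_site)
      full[sort(unique(site_of_read))] <- alt_count
      alt_count <- full
    }
    tibble::tibble(
      chrom = mk$chrom[site_idx],
      pos = mk$pos[site_idx],
      ref = mk$ref[site_idx],
      alt = mk$alt[site_idx],
      ref_count = as.integer(depth - alt_count),
      alt_count = alt_count
    )
  })
}

#' Simulate a complete two-bulk QTL-seq experiment
#'
#' Runs the whole generator: biparental cross to F3, quantitative trait
#' with one planted QTL, extreme-tail bulk formation (lowest tail =
#' hyper-sensitive, highest = hyper-resistant), and pooled sequencing of
#' both bulks over all map markers. Defaults reproduce the study design at
#' desk scale: 400 F3 from 400 selfed F2, 42 individuals per tail, Poisson
#' read depth with mean 100 per pool.
#'
#' @param map A [genetic_map()].
#' @param n_f2,n_f3 Population sizes.
#' @param qtl A [qtl_spec()].
#' @param pool_cfg A [poolseq_config()].
#' @param tail_count Individuals per bulk (overrides `tail_fraction`).
#' @param tail_fraction Tail fraction used when `tail_count` is `NULL`.
#' @param seed Integer master seed.
#' @return List with `counts` (allele-count table: `chrom`, `pos`, `ref`,
#'   `alt`, `ref_count_S`, `alt_count_S`, `ref_count_R`, `alt_count_R`),
#'   `phenotypes`, and `truth` (planted QTL, the marker it landed on, and
#'   bulk membership) for scoring localization downstream.
#' @export
simulate_bulk_experiment <- function(map = sim_genetic_map(),
                                     n_f2 = 400L, n_f3 = 400L,
                                     qtl = qtl_spec(),
                                     pool_cfg = poolseq_config(),
                                     tail_count = 42L, tail_fraction = 0.1,
                                     seed = 1L) {
  pop <- make_population(n_f2, n_f3, map, seed = seed)
  ph <- assign_phenotypes(pop, qtl, seed = seed)
  rr_like <- tibble::tibble(line_id = ph$id, rr = ph$phenotype)
  tails <- select_tails(rr_like,
    tail_fraction = tail_fraction,
    tail_count = tail_count
  )
  s_counts <- pool_and_sequence(pop, tails$sensitive,
    cfg = pool_cfg,
    seed = seed, stream = "poolseq:S"
  )
  r_counts <- pool_and_sequence(pop, tails$resistant,
    cfg = pool_cfg,
    seed = seed, stream = "poolseq:R"
  )
  counts <- tibble::tibble(
    chrom = s_counts$chrom, pos = s_counts$pos,
    ref = s_counts$ref, alt = s_counts$alt,
    ref_count_S = s_counts$ref_count, alt_count_S = s_counts$alt_count,
    ref_count_R = r_counts$ref_count, alt_count_R = r_counts$alt_count
  )
  list(
    counts = counts,
    phenotypes = ph,
    truth = list(
      qtl = qtl,
      qtl_marker = attr(ph, "qtl_marker"),
      sensitive_ids = tails$sensitive,
      resistant_ids = tails$resistant,
      seed = seed
    )
  )
}
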