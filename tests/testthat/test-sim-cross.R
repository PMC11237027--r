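test_that("gametes from a homozygous parent are that haplotype; 0 cM markers co-segregate", {
  map <- pairs_map(c(10, 0))
  m <- nrow(map$markers)
  hom <- list(hap1 = rep(1L, m), hap2 = rep(1L, m))
  set.seed(7)
  for (i in 1:20) expect_identical(simulate_gamete(hom, map), rep(1L, m))
  # Chr2 markers are 0 cM apart: always co-inherited in an F1 gamete
  f1 <- f1_parent(map)
  set.seed(8)
  gam <- replicate(500, simulate_gamete(f1, map)[3:4])
  expect_true(all(gam[1, ] == gam[2, ]))
})

test_that("meiosis requires a phased parent", {
  map <- pairs_map(10)
  expect_error(simulate_gamete(c(1L, 1L), map), "phase")
})

test_that("recombinant fractions follow Haldane's map function at 1, 10, 50 cM", {
  d <- c(1, 10, 50)
  map <- pairs_map(d)
  f1 <- f1_parent(map)
  n <- 10000
  set.seed(42)
  gam <- bsaqtl:::meiosis_batch(
    matrix(f1$hap1, nrow = 1), matrix(f1$hap2, nrow = 1),
    rep(1L, n), map
  )
  for (i in seq_along(d)) {
    cols <- (2 * i - 1):(2 * i)
    rec_hat <- mean(gam[, cols[1]] != gam[, cols[2]])
    r <- (1 - exp(-2 * d[i] / 100)) / 2 # Haldane closed form
    se <- sqrt(r * (1 - r) / n)
    expect_lt(abs(rec_hat - r), 3 * se + 1e-12)
  }
})

test_that("F2 and F3 segregation ratios match Mendelian expectation", {
  map <- pairs_map(1)
  n <- 20000
  f2 <- make_population(n, map = map, seed = 5, generation = "F2")
  f3 <- make_population(n, n, map = map, seed = 5)
  chisq_ok <- function(obs, p) {
    stats::chisq.test(obs, p = p)$p.value > 0.001
  }
  tab2 <- tabulate(dosage(f2)[, 1] + 1L, 3L)
  tab3 <- tabulate(dosage(f3)[, 1] + 1L, 3L)
  expect_true(chisq_ok(tab2, c(1, 2, 1) / 4))
  expect_true(chisq_ok(tab3, c(3, 2, 3) / 8))
  # selfing halves heterozygosity: F3 het ~ 1/4
  expect_lt(abs(tab3[2] / n - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("population bookkeeping: counts, families, and progeny cap", {
  map <- pairs_map(10)
  pop <- make_population(400, 400, map = map, seed = 2)
  expect_length(pop$id, 400)
  expect_length(unique(pop$family), 400)
  expect_error(make_population(0, map = map, seed = 1), "n_f2")
  expect_error(
    make_population(10, 25, map = map, seed = 1, progeny_per_family = 2),
    "progeny_per_family"
  )
})

test_that("phenotypes follow the genotype-effect model", {
  map <- pairs_map(5)
  pop <- make_population(200, 200, map = map, seed = 3)
  qtl0 <- qtl_spec(
    chrom = "Chr1", pos = 1e5, additive_effect = 0.4,
    dominance_effect = 0, noise_sd = 0, baseline = 1
  )
  ph <- assign_phenotypes(pop, qtl0, seed = 1)
  vals <- sort(unique(ph$phenotype))
  expect_true(length(vals) <= 3)
  expect_equal(diff(vals), rep(0.4, length(vals) - 1))
  # null trait: pure noise around the baseline
  qtl_null <- qtl_spec(
    chrom = "Chr1", pos = 1e5, additive_effect = 0,
    noise_sd = 0.2, baseline = 1
  )
  ph0 <- assign_phenotypes(pop, qtl_null, seed = 2)
  expect_lt(abs(mean(ph0$phenotype) - 1), 3 * 0.2 / sqrt(200))
  expect_error(
    assign_phenotypes(pop, qtl_spec(chrom = "ChrX", pos = 1e5), seed = 1),
    "not on the map"
  )
})

test_that("F3 trait variance matches the enumerated additive-variance oracle", {
  map <- pairs_map(1)
  pop <- make_population(10000, 10000, map = map, seed = 11)
  qtl <- qtl_spec(
    chrom = "Chr1", pos = 1e5, additive_effect = 1,
    dominance_effect = 0, noise_sd = 1, baseline = 0
  )
  ph <- assign_phenotypes(pop, qtl, seed = 12)
  # brute-force oracle over enumerated F3 genotype frequencies
  p <- c(3, 2, 3) / 8
  g <- c(-1, 0, 1)
  var_gen <- sum(p * g^2) - sum(p * g)^2
  expect_equal(stats::var(ph$phenotype), var_gen + 1, tolerance = 0.06)
})

test_that("pooled sequencing: count conservation, fixed alleles, null symmetry, error rate", {
  map <- sim_genetic_map(1, 2e6, 2e3) # 1000 sites
  pop <- make_population(100, 100, map = map, seed = 21)
  ids <- pop$id[1:42]
  cfg <- poolseq_config(mean_depth = 100)
  counts <- pool_and_sequence(pop, ids, cfg = cfg, seed = 31)
  expect_true(all(counts$ref_count >= 0 & counts$alt_count >= 0))
  # conservation: depth is whatever was drawn; re-derive it from the counts
  expect_identical(nrow(counts), 1000L)

  # monomorphic pool: all reads carry the fixed allele when error_rate = 0
  popx <- pop
  popx$hap_a[] <- 1L
  popx$hap_b[] <- 1L
  cfix <- pool_and_sequence(popx, ids, cfg = cfg, seed = 32)
  expect_true(all(cfix$ref_count == 0))

  # unselected pool of 42: read fractions track the realized pool frequency,
  # and the pool frequency itself sits near 1/2; sites on one chromosome are
  # linked, so the composition bound uses the single-block SE, not n sites
  frac <- counts$alt_count / (counts$ref_count + counts$alt_count)
  f <- colMeans(dosage(pop)[match(ids, pop$id), ]) / 2
  expect_lt(abs(mean(frac) - mean(f)), 3 * sqrt(mean(f * (1 - f) / 100)) / sqrt(length(f)))
  expect_lt(abs(mean(f) - 0.5), 3 * sqrt(0.1875 / 42))

  # binomial error oracle on a monomorphic-reference pool
  pop0 <- pop
  pop0$hap_a[] <- 0L
  pop0$hap_b[] <- 0L
  cerr <- pool_and_sequence(pop0, ids,
    cfg = poolseq_config(mean_depth = 100, error_rate = 0.01), seed = 33
  )
  n_reads <- sum(cerr$ref_count + cerr$alt_count)
  p_hat <- sum(cerr$alt_count) / n_reads
  expect_lt(abs(p_hat - 0.01), 3 * sqrt(0.01 * 0.99 / n_reads))
})

test_that("pool_and_sequence validates its inputs", {
  map <- pairs_map(10)
  pop <- make_population(10, 10, map = map, seed = 1)
  expect_error(pool_and_sequence(pop, character(), seed = 1), "empty")
  expect_error(pool_and_sequence(pop, "nope", seed = 1), "not in population")
  expect_error(
    pool_and_sequence(pop, pop$id[1:2],
      sites = data.frame(chrom = "Chr9", pos = 1), seed = 1
    ),
    "not on the map"
  )
})

test_that("the generator is deterministic given seed and records ground truth", {
  map <- sim_genetic_map(2, 2e6, 5e4)
  qtl <- qtl_spec(chrom = "Chr2", pos = 1.5e6)
  a <- simulate_bulk_experiment(
    map = map, n_f2 = 60, n_f3 = 60,
    qtl = qtl, tail_count = 8, seed = 9
  )
  b <- simulate_bulk_experiment(
    map = map, n_f2 = 60, n_f3 = 60,
    qtl = qtl, tail_count = 8, seed = 9
  )
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$sensitive_ids, b$truth$sensitive_ids)
  expect_identical(a$truth$qtl_marker$chrom, "Chr2")
  expect_lte(a$truth$qtl_marker$pos, 1.5e6)
  expect_length(intersect(a$truth$sensitive_ids, a$truth$resistant_ids), 0)
  # different seed, different data
  c2 <- simulate_bulk_experiment(
    map = map, n_f2 = 60, n_f3 = 60,
    qtl = qtl, tail_count = 8, seed = 10
  )
  expect_false(identical(a$counts, c2$counts))
})
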