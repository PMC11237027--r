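#' Write a table as TSV with a provenance header
#'
#' All pipeline writers emit comment lines (`# key: value`) ahead of the
#' header row; all readers skip and preserve them. No timestamps are
#' written, so reruns with the same configuration are byte-identical.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(df, path, provenance = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, paste(provenance[[k]], collapse = ",")), con)
  }
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path File path.
#' @return Tibble with attribute `provenance` (named character list parsed
#'   from leading `# key: value` lines).
#' @export
read_tsv_prov <- function(path) {
  head_lines <- character()
  con <- file(path, open = "rt")
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    head_lines <- c(head_lines, ln)
  }
  close(con)
  df <- tibble::as_tibble(utils::read.delim(path,
    comment.char = "#",
    stringsAsFactors = FALSE
  ))
  prov <- list()
  for (ln in head_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) prov[[m[2L]]] <- m[3L]
  }
  attr(df, "provenance") <- prov
  df
}

#' Read a two-bulk allele-count table
#'
#' Accepts either the pipeline's TSV layout (`chrom`, `pos`, `ref`, `alt`,
#' `ref_count_S`, `alt_count_S`, `ref_count_R`, `alt_count_R`) or a VCF 4.2
#' file with per-sample allele depths (`AD`), mapping samples to pools via
#' `pool_map`. Only biallelic SNP records are accepted from VCF;
#' multi-allelic records are skipped and counted in the `n_skipped`
#' attribute. Unsorted input is sorted with a warning.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param pool_map Named character vector mapping pools to VCF sample
#'   names, e.g. `c(S = "bulk_sensitive", R = "bulk_resistant")`.
#' @return Validated allele-count tibble.
#' @export
read_counts <- function(path, format = c("tsv", "vcf"),
                        pool_map = c(S = "S", R = "R")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_prov(path)
    df$chrom <- as.character(df$chrom)
    return(validate_counts(df))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the vcfR package")
  }
  stopifnot(all(c("S", "R") %in% names(pool_map)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  samples <- colnames(vcf@gt)[-1L]
  for (p in c("S", "R")) {
    if (!(pool_map[[p]] %in% samples)) {
      stop("sample ", pool_map[[p]], " (pool ", p, ") absent from VCF")
    }
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    stop("AD field missing for samples ", paste(pool_map, collapse = ", "))
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- nchar(fix[, "REF"]) == 1L & nchar(alt) == 1L & !multi
  n_skipped <- sum(!snp)
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    ref <- vapply(parts, function(p) suppressWarnings(as.integer(p[1L])), integer(1))
    altc <- vapply(parts, function(p) suppressWarnings(as.integer(p[2L])), integer(1))
    list(ref = ref, alt = altc)
  }
  ad_s <- parse_ad(ad[snp, pool_map[["S"]]])
  ad_r <- parse_ad(ad[snp, pool_map[["R"]]])
  if (anyNA(ad_s$ref) || anyNA(ad_r$ref)) {
    bad <- which(is.na(ad_s$ref) | is.na(ad_r$ref))
    stop("unparseable AD at record(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- tibble::tibble(
    chrom = as.character(fix[snp, "CHROM"]),
    pos = as.numeric(fix[snp, "POS"]),
    ref = fix[snp, "REF"],
    alt = alt[snp],
    ref_count_S = ad_s$ref, alt_count_S = ad_s$alt,
    ref_count_R = ad_r$ref, alt_count_R = ad_r$alt
  )
  out <- validate_counts(out)
  attr(out, "n_skipped") <- n_skipped
  if (n_skipped > 0L) {
    warning(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  out
}

#' Write an allele-count table as TSV
#'
#' @param counts Allele-count tibble.
#' @param path Output path.
#' @param provenance Named list for the header.
#' @export
write_counts <- function(counts, path, provenance = list()) {
  write_tsv_prov(validate_counts(counts), path, provenance)
}

#' Serialize / read confidence thresholds
#'
#' @param ci A `ci_thresholds`.
#' @param path File path.
#' @export
write_ci <- function(ci, path) {
  prov <- attr(ci, "provenance")
  write_tsv_prov(as.data.frame(ci), path, lapply(prov, paste, collapse = ","))
}

#' @rdname write_ci
#' @export
read_ci <- function(path) {
  df <- read_tsv_prov(path)
  class(df) <- c("ci_thresholds", class(df))
  df
}

#' Write called regions as a BED-like file
#'
#' Internal coordinates are 1-based inclusive; BED output converts to
#' 0-based half-open at this boundary only.
#'
#' @param regions Regions from [call_regions()].
#' @param path Output path.
#' @param provenance Named list for the header.
#' @export
write_regions_bed <- function(regions, path, provenance = list()) {
  bed <- tibble::tibble(
    chrom = regions$chrom,
    start = regions$start - 1,
    end = regions$end,
    name = sprintf("ci%g", regions$level),
    score = regions$peak_delta
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, paste(provenance[[k]], collapse = ",")), con)
  }
  utils::write.table(bed, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Genes overlapping candidate regions
#'
#' Reads a GFF3 annotation and reports every feature of the requested type
#' overlapping each region, on 1-based inclusive coordinates at both ends
#' (a gene starting exactly at a region end is included). Chromosome names
#' are reconciled through an explicit alias map, never guessed.
#'
#' @param regions Regions from [call_regions()].
#' @param annotation Path to a GFF3 file.
#' @param feature Feature type to report (default `"gene"`).
#' @param alias Optional named character vector mapping region chromosome
#'   names to annotation names, e.g. `c(Chr2 = "2")`.
#' @return Tibble: `region_chrom`, `region_start`, `region_end`,
#'   `gene_id`, `gene_name`, `gene_start`, `gene_end`, `strand`.
#' @export
genes_in_regions <- function(regions, annotation, feature = "gene", alias = NULL) {
  if (nrow(regions) == 0L) {
    return(tibble::tibble(
      region_chrom = character(), region_start = numeric(),
      region_end = numeric(), gene_id = character(), gene_name = character(),
      gene_start = numeric(), gene_end = numeric(), strand = character()
    ))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("annotation lookup requires the rtracklayer package")
  }
  gff <- rtracklayer::import(annotation, format = "gff3")
  gff <- gff[as.character(gff$type) == feature]
  reg_chrom <- regions$chrom
  if (!is.null(alias)) {
    hit <- reg_chrom %in% names(alias)
    reg_chrom[hit] <- alias[reg_chrom[hit]]
  }
  ann_chroms <- as.character(GenomicRanges::seqnames(gff))
  if (!any(reg_chrom %in% ann_chroms)) {
    stop(
      "no region chromosome matches the annotation (annotation uses: ",
      paste(utils::head(unique(ann_chroms), 5L), collapse = ", "),
      "); supply an alias map"
    )
  }
  out <- list()
  for (i in seq_len(nrow(regions))) {
    if (!(reg_chrom[i] %in% ann_chroms)) next
    q <- GenomicRanges::GRanges(
      reg_chrom[i],
      IRanges::IRanges(regions$start[i], regions$end[i])
    )
    ov <- GenomicRanges::findOverlaps(gff, q)
    g <- gff[S4Vectors::queryHits(ov)]
    if (length(g) == 0L) next
    ids <- if (!is.null(g$ID)) as.character(g$ID) else NA_character_
    nms <- if (!is.null(g$Name)) as.character(g$Name) else ids
    out[[length(out) + 1L]] <- tibble::tibble(
      region_chrom = regions$chrom[i],
      region_start = regions$start[i],
      region_end = regions$end[i],
      gene_id = ids,
      gene_name = nms,
      gene_start = GenomicRanges::start(g),
      gene_end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g))
    )
  }
  if (length(out) == 0L) {
    return(genes_in_regions(regions[0, ], annotation, feature, alias))
  }
  dplyr::bind_rows(out)
}

# small non-cryptographic hash (FNV-1a over a string) for config provenance
fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' @param counts Allele-count tibble, or a path readable by
#'   [read_counts()].
#' @param format Input format when `counts` is a path.
#' @param pool_map Sample-to-pool mapping for VCF input.
#' @param filters A [filter_config()].
#' @param window,step Scan geometry in bp.
#' @param chrom_lengths Optional named chromosome lengths.
#' @param null_cfg A [null_sim_config()]; its seed is re-derived from
#'   `seed` so one master seed drives the whole run.
#' @param call_levels Levels at which regions are called.
#' @param annotation Optional GFF3 path for the gene report.
#' @param alias Chromosome alias map for the annotation.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, format = "tsv", pool_map = c(S = "S", R = "R"),
                            filters = filter_config(), window = 1e6, step = 1e4,
                            chrom_lengths = NULL, null_cfg = null_sim_config(),
                            call_levels = c(0.95, 0.99), annotation = NULL,
                            alias = NULL, out_dir = tempfile("bsaqtl_run_"),
                            seed = 1L) {
  stopifnot(window >= step, step > 0)
  structure(
    list(
      counts = counts, format = format, pool_map = pool_map,
      filters = filters, window = window, step = step,
      chrom_lengths = chrom_lengths, null_cfg = null_cfg,
      call_levels = call_levels, annotation = annotation, alias = alias,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full QTL-seq pipeline
#'
#' Composes the analysis end-to-end: read/validate allele counts, build the
#' per-site delta track, simulate null confidence thresholds, average over
#' sliding windows, call candidate regions at each requested level, and
#' (optionally) report genes overlapping the regions. Every artifact is
#' written under `cfg$out_dir` as provenance-headed TSV (plus BED for the
#' regions); a rerun with the same configuration and seed reproduces every
#' file byte for byte. A failure in any stage aborts with the stage name;
#' artifacts of completed stages are left in place.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `track`, `ci`, `profile`, `regions`, `report`
#'   (or `NULL`), `log` (per-stage counters), and `out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  cfg_desc <- list(
    window = cfg$window, step = cfg$step,
    min_depth = cfg$filters$min_depth,
    min_total_index = cfg$filters$min_total_index,
    bulk_size = cfg$null_cfg$bulk_size,
    replications = cfg$null_cfg$replications,
    depth_grid = paste(range(cfg$null_cfg$depth_grid), collapse = "-"),
    call_levels = paste(cfg$call_levels, collapse = ","),
    seed = cfg$seed,
    counts = if (is.character(cfg$counts)) basename(cfg$counts) else "in-memory"
  )
  cfg_hash <- fnv1a(paste(names(cfg_desc), unlist(cfg_desc), collapse = ";"))
  prov <- list(config_hash = cfg_hash, seed = cfg$seed)

  counts <- stage("read_counts", {
    if (is.character(cfg$counts)) {
      read_counts(cfg$counts, format = cfg$format, pool_map = cfg$pool_map)
    } else {
      validate_counts(cfg$counts)
    }
  })
  log$sites_read <- nrow(counts)

  track <- stage("delta_track", build_delta_track(counts, cfg$filters))
  log$filter_summary <- attr(track, "filter_summary")
  write_tsv_prov(as.data.frame(track), file.path(cfg$out_dir, "delta_track.tsv"), prov)

  null_cfg <- cfg$null_cfg
  null_cfg$seed <- child_seed(cfg$seed, "null_ci")
  ci <- stage("null_ci", build_ci(null_cfg))
  write_ci(ci, file.path(cfg$out_dir, "ci_thresholds.tsv"))

  profile <- stage("window_scan", {
    window_average(track,
      window = cfg$window, step = cfg$step,
      chrom_lengths = cfg$chrom_lengths
    )
  })
  log$windows <- nrow(profile)
  log$windows_missing <- sum(is.na(profile$mean_delta))
  write_tsv_prov(as.data.frame(profile), file.path(cfg$out_dir, "window_profile.tsv"), prov)

  regions <- stage("call_regions", {
    dplyr::bind_rows(lapply(cfg$call_levels, function(lv) {
      call_regions(profile, ci, level = lv)
    }))
  })
  log$regions <- nrow(regions)
  write_tsv_prov(as.data.frame(regions), file.path(cfg$out_dir, "regions.tsv"), prov)
  write_regions_bed(regions, file.path(cfg$out_dir, "regions.bed"), prov)

  report <- NULL
  if (!is.null(cfg$annotation)) {
    report <- stage("gene_report", {
      genes_in_regions(regions, cfg$annotation, alias = cfg$alias)
    })
    log$genes <- nrow(report)
    write_tsv_prov(
      as.data.frame(report),
      file.path(cfg$out_dir, "region_genes.tsv"), prov
    )
  }

  yaml::write_yaml(
    c(prov, cfg_desc, log_flat(log)),
    file.path(cfg$out_dir, "provenance.yaml")
  )
  invisible(list(
    track = track, ci = ci, profile = profile, regions = regions,
    report = report, log = log, out_dir = cfg$out_dir
  ))
}

log_flat <- function(log) {
  if (!is.null(log$filter_summary)) {
    fs <- log$filter_summary
    log$filter_summary <- NULL
    log <- c(log, stats::setNames(fs, paste0("filter_", names(fs))))
  }
  log
}
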