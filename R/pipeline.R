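# Pipeline orchestration: panel -> (simulate or load) -> demultiplex ->
# trim -> align -> pileup -> dual-caller discovery -> cohort retention ->
# genotype -> annotate -> population tables -> reports + manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter; the defaults reproduce the assay's
#' published analysis settings: exact-barcode demultiplexing, trimming
#' `LEADING:3 TRAILING:3 SLIDINGWINDOW:4:20 MINLEN:36`, per-base phred
#' strictly greater than 30, both callers required, minimum allele depth
#' 10, minimum read depth 30, genotype classes `< 25%` / `25-75%` /
#' `> 75%` alternate reads, and chi-square with Yates correction.
#'
#' @param max_mismatch barcode mismatches allowed (0 or 1).
#' @param trim a [trim_params()].
#' @param band,k_seed,min_identity aligner settings (see [align_reads()]).
#' @param min_base_quality pileup per-base phred cutoff (strict >).
#' @param gap_pad pileup gap shadow in bp.
#' @param min_alt_frac caller A threshold.
#' @param caller_error_rate,caller_alpha caller B parameters.
#' @param combine `"intersection"` (default) or `"union"` of the callers.
#' @param min_alt_depth,min_depth per-sample depth filters.
#' @param fixed_hi,other_lo,min_called species-specific-site rule.
#' @param yates chi-square continuity correction flag.
#' @param seed seed recorded in the manifest (simulation seeds live in the
#'   [sim_config()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(max_mismatch = 0, trim = trim_params(),
                            band = 10, k_seed = 15, min_identity = 0.8,
                            min_base_quality = 30, gap_pad = 3,
                            min_alt_frac = 0.05, caller_error_rate = 0.005,
                            caller_alpha = 1e-3,
                            combine = c("intersection", "union"),
                            min_alt_depth = 10, min_depth = 30,
                            fixed_hi = 0.95, other_lo = 0.05, min_called = 5,
                            yates = TRUE, seed = 1L) {
  combine <- match.arg(combine)
  structure(list(max_mismatch = max_mismatch, trim = trim, band = band,
                 k_seed = k_seed, min_identity = min_identity,
                 min_base_quality = min_base_quality, gap_pad = gap_pad,
                 min_alt_frac = min_alt_frac,
                 caller_error_rate = caller_error_rate,
                 caller_alpha = caller_alpha, combine = combine,
                 min_alt_depth = min_alt_depth, min_depth = min_depth,
                 fixed_hi = fixed_hi, other_lo = other_lo,
                 min_called = min_called, yates = yates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat, sectioned config; unknown keys error, missing keys take the
#' defaults of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  trim_args <- y$trim %||% list()
  y$trim <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  y$trim <- do.call(trim_params, trim_args)
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full genotyping pipeline on one or more pools
#'
#' @param panel an `amplicon_panel`.
#' @param pools list of pools, each a list with `fastq1`, `fastq2` and
#'   `samples` (the pool's sample sheet: sample_id, fwd_barcode,
#'   rev_barcode, island, species) — e.g. the `pools` element of
#'   [simulate_cohort()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory for reports; `NULL` skips all file
#'   output.
#' @return invisibly, a list with `demux_report`, `trim_stats`,
#'   `discovered` (post-retention site table with annotation),
#'   `genotypes` (long per-sample calls at target + retained sites),
#'   `tables` (overall, by island, by species), `mutation_load`,
#'   `dropped_sites` and `manifest`.
#' @export
run_pipeline <- function(panel, pools, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %s done (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                    name, as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  all_samples <- do.call(rbind, lapply(pools, `[[`, "samples"))
  if (anyDuplicated(all_samples$sample_id))
    stop("duplicate sample ids across pools")

  # demultiplex each pool, then merge
  dmx <- stage("demultiplex", {
    lapply(pools, function(p)
      demultiplex(p$fastq1, p$fastq2, p$samples,
                  max_mismatch = config$max_mismatch))
  })
  seq1 <- unlist(lapply(dmx, `[[`, "seq1"), use.names = FALSE)
  qual1 <- unlist(lapply(dmx, `[[`, "qual1"), use.names = FALSE)
  seq2 <- unlist(lapply(dmx, `[[`, "seq2"), use.names = FALSE)
  qual2 <- unlist(lapply(dmx, `[[`, "qual2"), use.names = FALSE)
  sample <- unlist(lapply(dmx, `[[`, "sample"), use.names = FALSE)
  assigned <- !is.na(sample)
  demux_report <- do.call(rbind, lapply(seq_along(dmx), function(i)
    cbind(pool = i, dmx[[i]]$report)))

  seq1 <- seq1[assigned]; qual1 <- qual1[assigned]
  seq2 <- seq2[assigned]; qual2 <- qual2[assigned]
  sample <- sample[assigned]

  tr <- stage("trim", trim_pairs(seq1, qual1, seq2, qual2, config$trim))
  sample <- sample[tr$keep]
  trim_stats <- list(n_pairs_in = length(tr$keep),
                     n_pairs_dropped = tr$n_dropped)

  n_pairs <- length(tr$seq1)
  pair_id <- seq_len(n_pairs)
  aln <- stage("align", {
    a <- align_reads(c(tr$seq1, tr$seq2), panel, band = config$band,
                     k = config$k_seed, min_identity = config$min_identity)
    a
  })

  pileups_by_sample <- stage("pileup", {
    idx_all <- c(seq_len(n_pairs), seq_len(n_pairs))  # mate rows per pair
    seqs_all <- c(tr$seq1, tr$seq2)
    quals_all <- c(tr$qual1, tr$qual2)
    pid_all <- c(pair_id, pair_id)
    lapply(setNames(nm = all_samples$sample_id), function(s) {
      rows <- which(c(sample, sample) == s)
      build_pileup(aln[rows, , drop = FALSE], seqs_all[rows],
                   quals_all[rows], pid_all[rows], panel,
                   min_base_quality = config$min_base_quality,
                   gap_pad = config$gap_pad)
    })
  })

  discovered <- stage("call", {
    cand <- lapply(pileups_by_sample, function(p)
      call_sample_variants(p, panel, min_alt_frac = config$min_alt_frac,
                           error_rate = config$caller_error_rate,
                           alpha = config$caller_alpha,
                           min_alt_depth = config$min_alt_depth,
                           min_depth = config$min_depth,
                           combine = config$combine))
    u <- unique(do.call(rbind, cand)[, c("amplicon", "local", "pos",
                                         "chrom", "ref", "alt")])
    rownames(u) <- NULL
    u
  })

  # genotype all samples at discovered sites, apply cohort retention
  species <- setNames(all_samples$species, all_samples$sample_id)
  ret <- stage("retention", {
    if (nrow(discovered) == 0) {
      list(retained = character(0),
           dropped = data.frame(site = character(0), reason = character(0)))
    } else {
      g <- genotype_sites(pileups_by_sample, panel, discovered,
                          min_depth = config$min_depth)
      cohort_retention(g, species, fixed_hi = config$fixed_hi,
                       other_lo = config$other_lo,
                       min_called = config$min_called)
    }
  })
  dkey <- paste(discovered$amplicon, discovered$pos, discovered$alt, sep = ":")
  discovered <- discovered[dkey %in% ret$retained, , drop = FALSE]

  # final genotyping at retained + target sites
  targets <- panel$targets
  tsites <- data.frame(amplicon = targets$amplicon,
                       local = local_pos_vec(panel, targets$amplicon,
                                             targets$pos),
                       pos = targets$pos, chrom = targets$chrom,
                       ref = targets$ref, alt = targets$alt,
                       stringsAsFactors = FALSE)
  sites <- unique(rbind(tsites, discovered))
  genotypes <- stage("genotype", {
    g <- genotype_sites(pileups_by_sample, panel, sites,
                        min_depth = config$min_depth)
    ann <- annotate_sites(panel, sites)
    key <- paste(sites$amplicon, sites$pos, sites$alt, sep = ":")
    lab <- setNames(ifelse(is.na(ann$label), key, ann$label), key)
    g$label <- lab[paste(g$amplicon, g$pos, g$alt, sep = ":")]
    g
  })
  annotation <- annotate_sites(panel, sites)

  tables <- stage("popgen", {
    tg <- genotypes[genotypes$label %in% targets$label, , drop = FALSE]
    list(overall = stratified_table(tg, all_samples, "all"),
         by_island = stratified_table(tg, all_samples, "island"),
         by_species = stratified_table(tg, all_samples, "species"))
  })
  load_tab <- mutation_load(genotypes, panel)

  manifest <- list(
    n_pools = length(pools), n_samples = nrow(all_samples),
    parameters = config[setdiff(names(config), "trim")],
    trim = unclass(config$trim),
    n_pairs_assigned = sum(assigned), trim_stats = trim_stats,
    n_sites_discovered = length(dkey), n_sites_retained = nrow(discovered),
    dropped_sites = ret$dropped)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(demux_report, file.path(out_dir, "demux_report.tsv"))
    write_vcf(genotypes, panel, file.path(out_dir, "calls.vcf"),
              annotations = annotation)
    write_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_tsv(format_frequency_table(tables$overall),
              file.path(out_dir, "frequencies_overall.tsv"))
    write_tsv(format_frequency_table(tables$by_island),
              file.path(out_dir, "frequencies_by_island.tsv"))
    write_tsv(format_frequency_table(tables$by_species),
              file.path(out_dir, "frequencies_by_species.tsv"))
    write_tsv(load_tab, file.path(out_dir, "mutation_load.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(demux_report = demux_report, trim_stats = trim_stats,
                 discovered = discovered, genotypes = genotypes,
                 annotation = annotation, tables = tables,
                 mutation_load = load_tab, dropped_sites = ret$dropped,
                 manifest = manifest))
}

local_pos_vec <- function(panel, amplicon, genome_pos) {
  genome_pos - panel$amplicons$start[match(amplicon, panel$amplicons$id)] + 1L
}

# annotate a site table; positions outside all categories are labelled
# "unclassified" rather than aborting the run
annotate_sites <- function(panel, sites) {
  eff <- lab <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    a <- annotate_site(panel, sites$amplicon[i], sites$pos[i],
                       sites$ref[i], sites$alt[i], strict = FALSE)
    eff[i] <- a$effect
    lab[i] <- a$label
  }
  data.frame(amplicon = sites$amplicon, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, effect = eff, label = lab,
             stringsAsFactors = FALSE)
}

#' Estimated alternate-allele frequency of one target from pipeline output
#'
#' @param result a [run_pipeline()] result.
#' @param label target label (e.g. `"L995F"`).
#' @return frequency in percent (NA when no sample was called).
#' @export
estimated_frequency <- function(result, label) {
  tab <- result$tables$overall
  row <- tab[tab$label == label, , drop = FALSE]
  if (nrow(row) == 0) return(NA_real_)
  row$alt_freq_pct[1]
}
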