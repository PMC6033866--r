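#' Run configuration for an end-to-end analysis
#'
#' @param manifest Path to a manifest TSV (columns sample_id, group,
#'   area, locus, fastq, optional spike_fastq) or an equivalent
#'   data.frame, e.g. from [simulate_cohort()].
#' @param references Named list of [amplicon_reference()] objects (one
#'   per locus named in the manifest), or a FASTA path plus `ref_config`
#'   for [read_amplicon_references()].
#' @param spike_reference Optional spike-in [amplicon_reference()].
#' @param thresholds A [filter_thresholds()].
#' @param output_dir Directory the stage outputs are written to.
#' @param rarefaction_depth NULL for the minimum sample depth.
#' @param rarefaction_seed,anosim_permutations,cramer_resamples,test_seed
#'   Stochastic-stage settings; every seed used is recorded in the run
#'   report.
#' @param ref_config Sidecar configuration when `references` is a FASTA
#'   path.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, references, spike_reference = NULL,
                       thresholds = filter_thresholds(),
                       output_dir = "epidiv_out",
                       rarefaction_depth = NULL, rarefaction_seed = 1L,
                       anosim_permutations = 999L, cramer_resamples = 1000L,
                       test_seed = 1L, ref_config = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest file not found: ", manifest)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "group", "area", "locus", "fastq")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  if (is.character(references))
    references <- read_amplicon_references(references, ref_config)
  stopifnot(is.list(references), !is.null(names(references)))
  bad <- !file.exists(manifest$fastq)
  if (any(bad))
    stop("missing FASTQ file(s): ", paste(manifest$fastq[bad], collapse = ", "))
  if ("spike_fastq" %in% names(manifest)) {
    bad <- !is.na(manifest$spike_fastq) & !file.exists(manifest$spike_fastq)
    if (any(bad))
      stop("missing spike FASTQ file(s): ",
           paste(manifest$spike_fastq[bad], collapse = ", "))
  }
  missing_ref <- setdiff(unique(manifest$locus), names(references))
  if (length(missing_ref))
    stop("no reference for locus/loci: ", paste(missing_ref, collapse = ", "))
  structure(list(manifest = manifest, references = references,
                 spike_reference = spike_reference, thresholds = thresholds,
                 output_dir = output_dir,
                 rarefaction_depth = rarefaction_depth,
                 rarefaction_seed = as.integer(rarefaction_seed),
                 anosim_permutations = as.integer(anosim_permutations),
                 cramer_resamples = as.integer(cramer_resamples),
                 test_seed = as.integer(test_seed)),
            class = "run_config")
}

#' Run the full epiallele analysis pipeline
#'
#' Stages, in dependency order, per locus: read + quality-filter each
#' sample's FASTQ, bisulfite-align, call and QC-filter per-molecule
#' profiles, estimate spike-in conversion efficiency (when spike reads
#' are provided), build the sample-by-epiallele count table, rarefy it,
#' and compute class distributions, per-site/regional methylation, mCpH
#' summaries, alpha diversity, Bray-Curtis, PCoA, ANOSIM over areas and
#' the Cramér test between areas on class profiles. All tabular outputs
#' are written under the configured output directory together with a run
#' report (input hashes, thresholds, seeds, per-stage read counts);
#' re-running an identical configuration reproduces the outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list per locus with all stage results plus the
#'   run report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  mf <- config$manifest
  report <- list(
    thresholds = unclass(config$thresholds),
    seeds = list(rarefaction = config$rarefaction_seed,
                 tests = config$test_seed),
    input_hashes = as.list(tools::md5sum(mf$fastq)),
    samples = list()
  )
  results <- list()
  for (locus in unique(mf$locus)) {
    ref <- config$references[[locus]]
    sel <- mf[mf$locus == locus, , drop = FALSE]
    profs <- list(); conv <- list()
    for (i in seq_len(nrow(sel))) {
      sid <- sel$sample_id[i]
      ps <- tryCatch(
        process_sample(sel$fastq[i], ref, config$thresholds),
        error = function(e) stop("stage 'profiles' failed for sample '", sid,
                                 "', locus '", locus, "': ",
                                 conditionMessage(e), call. = FALSE))
      profs[[sid]] <- ps$profiles
      report$samples[[sid]] <- ps$report
      if (!is.null(config$spike_reference) && "spike_fastq" %in% names(sel) &&
          !is.na(sel$spike_fastq[i])) {
        spk <- quality_filter(read_sample_fastq(sel$spike_fastq[i]),
                              config$thresholds$min_mean_phred)$pass
        conv[[sid]] <- estimate_conversion_efficiency(spk, config$spike_reference,
                                                      sample_id = sid)
      }
    }
    # per-sample conversion reports, pooled fallback for samples without one
    pooled <- if (length(conv)) {
      eff <- mean(vapply(conv, `[[`, 0, "conversion_efficiency"))
      structure(list(sample_id = "pooled",
                     n_spike_reads = sum(vapply(conv, `[[`, 0, "n_spike_reads")),
                     conversion_efficiency = eff,
                     residual_c_fraction = 1 - eff),
                class = "conversion_report")
    } else NULL
    tab <- build_count_table(profs, ref)
    rtab <- rarefy(tab, depth = config$rarefaction_depth,
                   seed = config$rarefaction_seed)
    cdist <- class_distribution(rtab)
    alpha <- alpha_diversity(rtab)
    bc <- bray_curtis(rtab)
    ord <- pcoa(bc)
    area <- sel$area[match(rownames(rtab$counts), sel$sample_id)]
    an <- if (length(unique(area)) >= 2L && all(table(area) >= 2L))
      anosim(bc, area, config$anosim_permutations, seed = config$test_seed)
    else NULL
    cr <- list()
    ua <- unique(area)
    if (length(ua) >= 2L) {
      for (a in seq_along(ua)) for (b in seq_len(a - 1L)) {
        key <- paste(ua[b], ua[a], sep = "_vs_")
        cr[[key]] <- cramer_test(cdist$frequencies[area == ua[b], , drop = FALSE],
                                 cdist$frequencies[area == ua[a], , drop = FALSE],
                                 n_resamples = config$cramer_resamples,
                                 seed = config$test_seed)
      }
    }
    summaries <- lapply(names(profs), function(sid)
      mch_summary(profs[[sid]],
                  conv[[sid]] %||% pooled))
    names(summaries) <- names(profs)
    site_pct <- t(vapply(profs, per_site_methylation, numeric(ref$n_cpg),
                         reference = ref))
    region_pct <- vapply(profs, region_average_methylation, numeric(1))

    .write_locus_outputs(config$output_dir, locus, rtab, cdist, alpha, bc,
                         ord, an, cr, site_pct, region_pct, summaries)
    results[[locus]] <- list(profiles = profs, conversion = conv,
                             conversion_pooled = pooled,
                             count_table = tab, rarefied = rtab,
                             class_distribution = cdist, alpha = alpha,
                             bray_curtis = bc, pcoa = ord, anosim = an,
                             cramer = cr, site_percent = site_pct,
                             region_percent = region_pct,
                             mch = summaries)
  }
  report$date <- format(Sys.time())
  jsonlite::write_json(report, file.path(config$output_dir, "run_report.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  results$report <- report
  invisible(results)
}

.write_locus_outputs <- function(dir, locus, rtab, cdist, alpha, bc, ord,
                                 an, cr, site_pct, region_pct, summaries) {
  p <- function(...) file.path(dir, paste0(locus, ".", ...))
  write_biom_table(rtab, p("counts.biom.json"))
  utils::write.table(data.frame(sample_id = rownames(rtab$counts),
                                rtab$counts, check.names = FALSE),
                     p("counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(cdist$frequencies),
                                cdist$frequencies, check.names = FALSE),
                     p("class_distribution.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(alpha, p("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(unclass(bc)), p("bray_curtis.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(data.frame(sample_id = rownames(ord$points), ord$points),
                     p("pcoa.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(site_pct), site_pct,
                                region_percent = region_pct, check.names = FALSE),
                     p("methylation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mch <- do.call(rbind, lapply(names(summaries), function(s)
    data.frame(sample_id = s, as.data.frame(unclass(summaries[[s]])))))
  utils::write.table(mch, p("mch_summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(an))
    jsonlite::write_json(list(test = "anosim", R = an$statistic,
                              p_value = an$p_value,
                              n_permutations = an$n_permutations,
                              seed = an$seed),
                         p("anosim.json"), auto_unbox = TRUE, digits = NA)
  if (length(cr))
    jsonlite::write_json(lapply(cr, function(x)
      list(test = "cramer", statistic = x$statistic, p_value = x$p_value,
           n_resamples = x$n_resamples, seed = x$seed)),
      p("cramer.json"), auto_unbox = TRUE, digits = NA)
}
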