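#' Build an analysis configuration
#'
#' A single declarative object drives [run_full_analysis()].  It can be
#' built in R or loaded from a YAML file with [read_analysis_config()].
#' Group membership (which populations form each analysis subgroup) is
#' always configuration, never inferred.
#'
#' @param input list describing the genotype input: either
#'   `list(format = "vcf", path = ...)` or
#'   `list(format = "plink", ped = ..., map = ...)`.
#' @param sample_map path to a sample-to-population TSV (see
#'   [read_sample_map()]), or a data.frame; `NULL` keeps labels from the
#'   input file.
#' @param groups named list: group name -> character vector of member
#'   populations (used for shared ROH islands and correlation matrices).
#' @param fst_pairs list of two-element lists; each element is a character
#'   vector of populations pooled into one side of a windowed F_ST scan.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed applied before any stochastic step.
#' @param roh a [roh_params()].
#' @param island_quantile,island_min_incidence,island_merge_gap_kb ROH
#'   island thresholds (see [detect_islands()]).
#' @param ne_t_range,ne_alpha,ne_cm_per_mb,ne_correction Ne-estimation
#'   settings (see [estimate_ne()]).
#' @param autosomes autosome labels for QC rule 6 and `L_auto`.
#' @param diversity_mode `"heterozygosity"` or `"homozygosity"`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, sample_map = NULL, groups = list(),
                            fst_pairs = list(), out_dir = "genodiv_results",
                            seed = 1L, roh = roh_params(),
                            island_quantile = 0.99,
                            island_min_incidence = 0.35,
                            island_merge_gap_kb = 100,
                            ne_t_range = 25:100, ne_alpha = 1,
                            ne_cm_per_mb = 1,
                            ne_correction = "one_over_n",
                            autosomes = pig_autosomes(),
                            diversity_mode = "heterozygosity") {
  cfg <- list(input = input, sample_map = sample_map, groups = groups,
              fst_pairs = fst_pairs, out_dir = out_dir,
              seed = as.integer(seed), roh = roh,
              island_quantile = island_quantile,
              island_min_incidence = island_min_incidence,
              island_merge_gap_kb = island_merge_gap_kb,
              ne_t_range = ne_t_range, ne_alpha = ne_alpha,
              ne_cm_per_mb = ne_cm_per_mb, ne_correction = ne_correction,
              autosomes = autosomes, diversity_mode = diversity_mode)
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$roh)) args$roh <- do.call(roh_params, y$roh)
  if (!is.null(y$ne_t_range) && length(y$ne_t_range) == 2L)
    args$ne_t_range <- seq(y$ne_t_range[[1L]], y$ne_t_range[[2L]])
  do.call(analysis_config, args)
}

load_config_input <- function(cfg) {
  popmap <- cfg$sample_map
  if (is.character(popmap)) popmap <- read_sample_map(popmap)
  inp <- cfg$input
  gm <- switch(inp$format,
               vcf = read_vcf(inp$path, population = popmap),
               plink = read_plink_text(inp$ped, inp$map,
                                       population = popmap),
               stop("unknown input format: ", inp$format))
  gm
}

#' Run the full per-population and per-group analysis
#'
#' For every population: QC report, diversity summary, ROH segments and
#' their length-class summary, the ten inbreeding coefficients (plus
#' per-population means), LD decay and the Ne trajectory, and ROH
#' islands.  For every configured group: shared ROH islands and the
#' inbreeding-coefficient correlation matrix.  For every configured pair
#' of population pools: the windowed F_ST scan with top-1% outliers, and
#' shared outlier regions between consecutive scans.  All results are
#' TSV/BED files under `out_dir`; a JSON manifest (config echo, seed,
#' package version) makes a run reproducible.
#'
#' The per-population analyses use each population's own post-QC SNP set;
#' cross-population scans use the intersection of the two pools' SNP
#' sets.  A stage failure for one population is logged and that
#' population's dependent outputs are skipped.
#'
#' @param cfg an [analysis_config()].
#' @return The output directory, invisibly.  Errors in every population
#'   (i.e. nothing produced) raise an error.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    message(line)
  }
  set.seed(cfg$seed)
  gm_all <- load_config_input(cfg)
  pops <- unique(gm_all$samples$population)
  for (grp in names(cfg$groups)) {
    missing_pops <- setdiff(cfg$groups[[grp]], pops)
    if (length(missing_pops))
      stop("group '", grp, "' references unknown population(s): ",
           paste(missing_pops, collapse = ", "))
  }
  for (pair in cfg$fst_pairs) {
    missing_pops <- setdiff(unlist(pair), pops)
    if (length(missing_pops))
      stop("fst pair references unknown population(s): ",
           paste(missing_pops, collapse = ", "))
  }
  logmsg("loaded ", nrow(gm_all$samples), " samples, ",
         nrow(gm_all$variants), " SNPs, ", length(pops), " populations")

  default_prof <- qc_profile("default", autosomes = cfg$autosomes)
  roh_prof <- qc_profile("roh", autosomes = cfg$autosomes)
  per_pop <- list()
  failed <- character()
  for (p in pops) {
    res <- tryCatch({
      gm_p <- subset_genotypes(gm_all,
                               sample_filter = function(s)
                                 s$population == p)
      qc_main <- apply_qc(gm_p, default_prof)
      qc_roh <- apply_qc(gm_p, roh_prof)
      segs <- detect_roh(qc_roh$gm, cfg$roh)
      inc <- roh_incidence(segs, qc_roh$gm)
      isl <- detect_islands(inc, qc_roh$gm$variants,
                            quantile = cfg$island_quantile,
                            min_incidence = cfg$island_min_incidence,
                            merge_gap_kb = cfg$island_merge_gap_kb)
      recs <- inbreeding_records(qc_main$gm, segs, roh_gm = qc_roh$gm,
                                 autosomes = cfg$autosomes)
      decay <- ld_decay(qc_main$gm)
      ne <- estimate_ne(qc_main$gm, t_range = cfg$ne_t_range,
                        alpha = cfg$ne_alpha,
                        cm_per_mb = cfg$ne_cm_per_mb,
                        sample_size_correction = cfg$ne_correction)
      pd <- file.path(cfg$out_dir, p)
      dir.create(pd, showWarnings = FALSE)
      write_tsv(qc_report_table(qc_main$report),
                file.path(pd, "qc_report.tsv"))
      write_tsv(diversity_summary(qc_main$gm, cfg$diversity_mode),
                file.path(pd, "diversity.tsv"))
      write_tsv(segs, file.path(pd, "roh_segments.tsv"))
      if (nrow(segs))
        write_bed(segs, file.path(pd, "roh_segments.bed"),
                  name_col = "sample_id")
      write_tsv(roh_summary(segs), file.path(pd, "roh_summary.tsv"))
      write_tsv(isl, file.path(pd, "roh_islands.tsv"))
      write_tsv(recs, file.path(pd, "inbreeding.tsv"))
      means <- data.frame(population = p,
                          t(colMeans(recs[, -1, drop = FALSE])))
      write_tsv(means, file.path(pd, "inbreeding_means.tsv"))
      write_tsv(decay, file.path(pd, "ld_decay.tsv"))
      write_tsv(ne, file.path(pd, "ne_trajectory.tsv"))
      logmsg("population ", p, ": ", nrow(segs), " ROH segments, ",
             nrow(isl), " islands")
      list(gm = qc_main$gm, roh_gm = qc_roh$gm, segments = segs,
           islands = isl, records = recs)
    }, error = function(e) {
      logmsg("population ", p, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, p) else per_pop[[p]] <- res
  }
  if (!length(per_pop)) stop("every population failed; see ", logfile)

  for (grp in names(cfg$groups)) {
    members <- intersect(cfg$groups[[grp]], names(per_pop))
    if (length(members) < 2L) {
      logmsg("group ", grp, " skipped (fewer than 2 usable populations)")
      next
    }
    sh <- shared_islands(lapply(per_pop[members], `[[`, "islands"))
    write_tsv(sh, file.path(cfg$out_dir,
                            paste0("shared_islands_", grp, ".tsv")))
    if (nrow(sh))
      write_bed(sh, file.path(cfg$out_dir,
                              paste0("shared_islands_", grp, ".bed")))
    recs <- do.call(rbind, lapply(per_pop[members], `[[`, "records"))
    cc <- inbreeding_correlations(recs)
    utils::write.table(cc, file.path(cfg$out_dir,
                                     paste0("inbreeding_correlations_",
                                            grp, ".tsv")),
                       quote = FALSE, sep = "\t", col.names = NA)
    logmsg("group ", grp, ": ", nrow(sh), " shared islands")
  }

  scans <- list()
  for (i in seq_along(cfg$fst_pairs)) {
    pair <- cfg$fst_pairs[[i]]
    tag <- paste(sapply(pair, paste, collapse = "+"), collapse = "_vs_")
    scan <- tryCatch({
      gm1 <- subset_genotypes(gm_all, sample_filter = function(s)
        s$population %in% pair[[1L]])
      gm2 <- subset_genotypes(gm_all, sample_filter = function(s)
        s$population %in% pair[[2L]])
      shared <- intersect(gm1$variants$snp_id, gm2$variants$snp_id)
      gm1 <- subset_genotypes(gm1, variant_filter = function(v)
        v$snp_id %in% shared)
      gm2 <- subset_genotypes(gm2, variant_filter = function(v)
        v$snp_id %in% shared)
      w <- outlier_windows(windowed_fst(gm1, gm2))
      write_tsv(w, file.path(cfg$out_dir, paste0("fst_", tag, ".tsv")))
      out <- merge_intervals(w[w$is_outlier,
                               c("chromosome", "start_bp", "end_bp")])
      if (nrow(out))
        write_bed(out, file.path(cfg$out_dir,
                                 paste0("fst_outliers_", tag, ".bed")))
      logmsg("fst scan ", tag, ": ", nrow(w), " windows, ",
             sum(w$is_outlier), " outliers")
      w
    }, error = function(e) {
      logmsg("fst scan ", tag, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (!is.null(scan)) scans[[tag]] <- scan
  }
  if (length(scans) >= 2L) {
    tags <- names(scans)
    for (i in seq_len(length(scans) - 1L)) {
      sh <- shared_outliers(scans[[i]], scans[[i + 1L]])
      write_tsv(sh, file.path(cfg$out_dir,
                              paste0("shared_fst_outliers_", tags[i],
                                     "__", tags[i + 1L], ".tsv")))
    }
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("genodiv")),
                   r_version = as.character(getRversion()),
                   seed = cfg$seed,
                   populations = pops,
                   failed_populations = failed,
                   config = cfg[setdiff(names(cfg), "roh")],
                   roh_params = unclass(cfg$roh))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (length(failed))
    warning("stage failures for population(s): ",
            paste(failed, collapse = ", "))
  invisible(cfg$out_dir)
}
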