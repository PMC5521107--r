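#' Pipeline run configuration
#'
#' Validates a configuration list (or YAML file) for [run_pipeline()].
#' Recognised keys: `ped`, `map` (input paths; or `genotype_table` +
#' `snp_map`), `breed_comp` (optional TSV), `linkage_map` (TSV of
#' anchors, required for M2/M3), `mode` (`per_breed`/`combined`),
#' `methods` (subset of M1/M2/M3), `qc` (overrides for [qc_config()]),
#' `ld` (`n_pairs`, `n_reps`, `grid_min`, `grid_max`, `grid_points`,
#' `span`), `compare` (`n_boot`, `points`), `seed`, `outdir`. Unknown
#' keys are rejected.
#'
#' @param config a list or the path of a YAML file.
#' @return Validated configuration list of class `"run_config"`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("ped", "map", "genotype_table", "snp_map", "breed_comp",
             "linkage_map", "mode", "methods", "qc", "ld", "compare",
             "seed", "outdir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$outdir)) stop("config needs 'outdir'")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$methods)) config$methods <- c("M1", "M2", "M3")
  stopifnot(all(config$methods %in% c("M1", "M2", "M3")))
  if (is.null(config$mode)) config$mode <- "per_breed"
  has_ped <- !is.null(config$ped) && !is.null(config$map)
  has_tab <- !is.null(config$genotype_table) && !is.null(config$snp_map)
  if (!has_ped && !has_tab)
    stop("config needs either ped+map or genotype_table+snp_map")
  if (any(config$methods %in% c("M2", "M3")) &&
      is.null(config$linkage_map))
    stop("methods M2/M3 need a linkage_map")
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: QC, diversity (He, GRM, inbreeding, MDS, outlier
#' flags), genetic maps (for each requested method), LD decay per
#' method, Ne history per method, and a method comparison when at least
#' two methods ran. Each stage writes its tabular outputs under
#' `outdir`; a JSON run manifest (config echo, package version, stage
#' status, output checksums) is written even when a stage fails, with
#' the failed stage marked. Stage seeds are derived from the single
#' config seed by fixed offsets.
#'
#' @param config a [run_config()] (or list / YAML path accepted by it).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg),
                   package_version =
                     as.character(utils::packageVersion("nehist")),
                   seed = cfg$seed, stages = list(), outputs = list())
  stage <- "read"
  on_fail <- function(e) {
    manifest$stages[[stage]] <- paste("FAILED:", conditionMessage(e))
    write_manifest(manifest, cfg$outdir)
    stop(e)
  }
  tryCatch({
    g <- if (!is.null(cfg$ped)) read_ped_map(cfg$ped, cfg$map) else
      read_geno_table(cfg$genotype_table, cfg$snp_map)
    if (!is.null(cfg$breed_comp)) g <- read_breed_comp(cfg$breed_comp, g)
    manifest$stages[[stage]] <- "ok"

    stage <- "qc"
    qc_args <- c(cfg$qc, list(mode = cfg$mode, seed = cfg$seed + 11L))
    qcc <- do.call(qc_config, qc_args[!duplicated(names(qc_args))])
    groups <- if (!is.null(g$breed_comp))
      assign_breed_group(g$breed_comp) else NULL
    qc <- apply_qc(g, qcc, groups = groups)
    write_qc_report(qc$report, file.path(cfg$outdir, "qc_report.json"))
    qc_counts_table(qc$report, file.path(cfg$outdir, "qc_counts.tsv"))
    g <- qc$geno
    manifest$stages[[stage]] <- "ok"

    stage <- "diversity"
    grm <- compute_grm(g, freq_model = if (!is.null(g$breed_comp))
      "breed_regression" else "pooled")
    dmat <- distance_matrix(grm)
    groups2 <- if (!is.null(g$breed_comp))
      assign_breed_group(g$breed_comp) else
        rep("all", nrow(g$dosage))
    dsum <- diversity_summary(g, grm, groups2)
    utils::write.table(dsum, file.path(cfg$outdir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(grm, file.path(cfg$outdir, "grm.tsv"))
    if (nrow(g$dosage) >= 3)
      write_mds_tsv(classical_mds(dmat, k = 2),
                    file.path(cfg$outdir, "mds.tsv"))
    out <- flag_outliers(dmat, groups2, 0.01)
    if (length(out))
      g <- subset_geno(g, animals = setdiff(g$animals$animal_id, out))
    manifest$stages[[stage]] <- "ok"

    stage <- "map"
    g_ld <- filter_maf(subset_geno(g, snps = autosomal_snps(g)),
                       if (!is.null(cfg$qc$maf_min_ld))
                         cfg$qc$maf_min_ld else 0.05)
    maps <- list()
    if ("M1" %in% cfg$methods) maps$M1 <- m1_positions(g_ld)
    if (any(c("M2", "M3") %in% cfg$methods)) {
      lk <- read_linkage_map(cfg$linkage_map)
      phys <- tapply(g_ld$snps$position_bp / 1e6,
                     g_ld$snps$chromosome, max)
      ratios <- chromosome_ratios(lk, physical_mb =
                                    phys[names(phys) %in%
                                           unique(lk$chromosome)])
      if ("M2" %in% cfg$methods) maps$M2 <- m2_positions(g_ld, ratios)
      if ("M3" %in% cfg$methods) maps$M3 <- m3_positions(lk, g_ld)
      ms <- map_summary(lk, g_ld)
      utils::write.table(ms, file.path(cfg$outdir, "map_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (m in names(maps)) {
      write_ucsc_track(maps[[m]],
                       file.path(cfg$outdir, paste0("map_", m, ".track.txt")),
                       name = paste0("genetic_map_", m))
    }
    manifest$stages[[stage]] <- "ok"

    stage <- "ld"
    ldp <- cfg$ld
    fits <- list()
    for (m in names(maps)) {
      fits[[m]] <- ld_decay(
        g_ld, maps[[m]],
        grid_min = ldp$grid_min %||% 0.5,
        grid_max = ldp$grid_max %||% 50,
        grid_points = ldp$grid_points %||% 2000,
        n_pairs = ldp$n_pairs %||% 20000,
        n_reps = ldp$n_reps %||% 30,
        seed = cfg$seed + 101L, span = ldp$span %||% 0.3)
      write_ld_grid(fits[[m]],
                    file.path(cfg$outdir, paste0("ld_", m, ".tsv")))
    }
    manifest$stages[[stage]] <- "ok"

    stage <- "ne"
    nes <- lapply(fits, ne_history)
    for (m in names(nes)) {
      write_ne_curve(nes[[m]],
                     file.path(cfg$outdir, paste0("ne_", m, ".tsv")))
    }
    tab4 <- do.call(rbind, lapply(names(nes), function(m)
      cbind(method = m, extract_at_generations(nes[[m]]))))
    utils::write.table(tab4, file.path(cfg$outdir, "ne_at_generations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages[[stage]] <- "ok"

    stage <- "compare"
    if (length(fits) >= 2 && length(fits[[1]]$chromosomes) >= 3) {
      cmb <- utils::combn(names(fits), 2)
      comp <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
        a <- cmb[1, i]; b <- cmb[2, i]
        cbind(pair = paste(a, b, sep = "_vs_"),
              compare_methods(fits[[a]], fits[[b]],
                              n_boot = cfg$compare$n_boot %||% 1000,
                              at = cfg$compare$points,
                              seed = cfg$seed + 301L))
      }))
      utils::write.table(comp, file.path(cfg$outdir, "method_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages[[stage]] <- "ok"
    } else {
      manifest$stages[[stage]] <-
        "skipped: needs at least two methods and three chromosomes"
    }
  }, error = on_fail)

  files <- list.files(cfg$outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- lapply(stats::setNames(files, basename(files)),
                             function(f) unname(tools::md5sum(f)))
  write_manifest(manifest, cfg$outdir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
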