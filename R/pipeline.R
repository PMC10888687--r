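#' Read a per-cell event table from CSV
#'
#' Reads an event table (one row per cell, one column per channel) and
#' renames columns according to `channel_map` (names = canonical channel
#' names used by the statistics functions, values = column names in the
#' file). Unmapped columns are preserved but ignored downstream.
#'
#' @param path CSV file path.
#' @param channel_map optional named character vector; `NULL` keeps the file
#'   column names.
#' @return event tibble.
#' @export
read_event_data <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(ev) == 0) stop("empty event table: ", path)
  if (!is.null(channel_map)) {
    missing_ch <- setdiff(unname(channel_map), names(ev))
    if (length(missing_ch))
      stop("channel(s) absent from ", basename(path), ": ",
           paste(missing_ch, collapse = ", "))
    for (i in seq_along(channel_map))
      names(ev)[names(ev) == channel_map[[i]]] <- names(channel_map)[i]
  }
  ev
}

#' Write the event tables of a synthetic study to CSV
#'
#' One file per sample x assay (`<sample_id>_<assay>.csv`, columns =
#' channels plus the latent `.state`), plus `design.csv` and `truth.csv`.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$samples, file.path(dir, "design.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  for (sid in names(study$events)) {
    for (assay in names(study$events[[sid]]))
      readr::write_csv(study$events[[sid]][[assay]],
                       file.path(dir, sprintf("%s_%s.csv", sid, assay)))
    readr::write_csv(study$kinematics[[sid]],
                     file.path(dir, sprintf("%s_casa.csv", sid)))
  }
  invisible(dir)
}

#' Default analysis configuration
#'
#' Gating cuts, stainability and band cuts, daily-standard reference
#' medians, clustering knobs and model options for the full pipeline. All
#' values are on the 10-bit channel scale and match the defaults of the
#' synthetic generator, standing in for the per-session calibration an
#' instrument workflow would supply.
#'
#' @param seed integer seed for the stochastic stages (clustering).
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    channel_max = 1023,
    gates = list(
      scsa = list(channels = c("green", "red"), cut = 30),
      mbbr = list(channels = "nuclear", cut = 30),
      cma3 = list(channels = "nuclear", cut = 30),
      oxodg = list(channels = "nuclear", cut = 30),
      phys = list(channels = "fsc", cut = 130)),
    scsa = list(hds_fraction = 0.65),
    mbbr = list(reference_mfi = 210, bounds = c(120, 450),
                disulfide_reference = 1),
    cma3 = list(reference_mfi = 277, bounds = c(150, 550)),
    oxodg = list(reference_mfi = 68, high_cut = 380),
    phys = list(stain_cut = 110, ros_reference = 60),
    motility = list(stage1_k = 40, k_range = 2:6, motile_vcl_cut = 10),
    multivariate = list(alpha = 0.05, n_pcs = 2, k_obs = 2)),
    class = "run_config")
}

.CHROMATIN_VARIABLES <- c("sd_dfi", "pct_dfi", "pct_hds",
                          "mbbr_low", "mbbr_moderate", "mbbr_high",
                          "mbbr_mfi", "disulfide",
                          "cma3_low", "cma3_moderate", "cma3_high",
                          "cma3_mfi", "oxodg_mfi")

#' Chromatin variable set
#'
#' The 13 per-sample chromatin status variables carried into the
#' multivariate analyses.
#' @return character vector.
#' @export
chromatin_variables <- function() .CHROMATIN_VARIABLES

.gate <- function(events, g, min_events) {
  gate_events(events, gating_strategy(g$channels, g$cut), min_events)
}

#' Per-sample statistics for one set of assay event tables
#'
#' Gates each assay table and computes the full chromatin + physiology
#' statistic row for one sample.
#'
#' @param assays named list with event tibbles `scsa`, `mbbr_untreated`,
#'   `mbbr_dtt`, `cma3`, `oxodg`, `phys1`, `phys2`.
#' @param config a [default_config()].
#' @param min_events acquisition floor for the gating warning.
#' @return list with `stats` (one-row tibble) and `gating` (per-assay
#'   reports).
#' @export
sample_statistics <- function(assays, config = default_config(),
                              min_events = 5000) {
  g <- config$gates
  gating <- list()
  gs <- .gate(assays$scsa, g$scsa, min_events); gating$scsa <- gs$report
  scsa <- scsa_statistics(gs$events,
                          config$scsa$hds_fraction * config$channel_max)
  gu <- .gate(assays$mbbr_untreated, g$mbbr, min_events)
  gd <- .gate(assays$mbbr_dtt, g$mbbr, min_events)
  gating$mbbr_untreated <- gu$report; gating$mbbr_dtt <- gd$report
  mbbr <- mbbr_statistics(gu$events, gd$events, config$mbbr$reference_mfi,
                          config$mbbr$bounds, config$mbbr$disulfide_reference)
  gc3 <- .gate(assays$cma3, g$cma3, min_events); gating$cma3 <- gc3$report
  cma3 <- cma3_statistics(gc3$events, config$cma3$reference_mfi,
                          config$cma3$bounds)
  go <- .gate(assays$oxodg, g$oxodg, min_events); gating$oxodg <- go$report
  oxo <- oxodg_statistics(go$events, config$oxodg$reference_mfi,
                          config$oxodg$high_cut)
  gp1 <- .gate(assays$phys1, g$phys, min_events)
  gp2 <- .gate(assays$phys2, g$phys, min_events)
  gating$phys1 <- gp1$report; gating$phys2 <- gp2$report
  phys <- physiology_statistics(gp1$events, gp2$events,
                                config$phys$stain_cut,
                                config$phys$ros_reference)
  stats_row <- tibble::tibble(
    sd_dfi = scsa$sd_dfi, pct_dfi = scsa$pct_dfi, pct_hds = scsa$pct_hds,
    mbbr_low = mbbr$pct_low, mbbr_moderate = mbbr$pct_moderate,
    mbbr_high = mbbr$pct_high, mbbr_mfi = mbbr$mfi_norm,
    disulfide = mbbr$disulfide_index,
    cma3_low = cma3$pct_low, cma3_moderate = cma3$pct_moderate,
    cma3_high = cma3$pct_high, cma3_mfi = cma3$mfi_norm,
    oxodg_mfi = oxo$mfi_norm, oxodg_high = oxo$pct_high,
    pct_viable = phys$pct_viable,
    pct_apoptotic_of_viable = phys$pct_apoptotic_of_viable,
    pct_acrosome_damaged_total = phys$pct_acrosome_damaged_total,
    pct_acrosome_damaged_of_nonapoptotic =
      phys$pct_acrosome_damaged_of_nonapoptotic,
    pct_capacitated_of_nonapoptotic = phys$pct_capacitated_of_nonapoptotic,
    pct_active_mitochondria = phys$pct_active_mitochondria,
    pct_high_superoxide_of_viable = phys$pct_high_superoxide_of_viable,
    cytoplasmic_ros_mfi = phys$cytoplasmic_ros_mfi)
  list(stats = stats_row, gating = gating)
}

#' Assemble the per-sample statistics table of a study
#'
#' Runs [sample_statistics()] for every sample; samples whose gating fails
#' are excluded and listed, never silently dropped. Fails only if every
#' sample fails.
#'
#' @param study a [generate_study()] result (or a compatible list with
#'   `samples`, `events`).
#' @param config a [default_config()].
#' @return list: `sample_table` (design columns + statistics), `gating_log`,
#'   `qc_excluded` (tibble of sample_id + error message).
#' @export
build_sample_table <- function(study, config = default_config()) {
  min_events <- min(5000, study$design$events_per_sample)
  rows <- list(); gating <- list(); failed <- list()
  for (i in seq_len(nrow(study$samples))) {
    sid <- study$samples$sample_id[i]
    res <- tryCatch(
      withCallingHandlers(
        sample_statistics(study$events[[sid]], config, min_events),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[[sid]] <- conditionMessage(res)
    } else {
      rows[[sid]] <- dplyr::bind_cols(study$samples[i, ], res$stats)
      gating[[sid]] <- res$gating
    }
  }
  if (!length(rows)) stop("all samples failed gating")
  qc <- tibble::tibble(
    sample_id = if (length(failed)) names(failed) else character(0),
    error = if (length(failed)) unlist(failed, use.names = FALSE)
            else character(0))
  list(sample_table = dplyr::bind_rows(rows), gating_log = gating,
       qc_excluded = qc)
}

#' Motility analysis for a study
#'
#' Derives motility classes per cell, pools motile cells over all samples,
#' fits the two-stage subpopulation model, and returns per-sample motility
#' summaries (percent motile and progressive, subpopulation percentages)
#' plus the cluster summary table.
#'
#' @param study a [generate_study()] result.
#' @param config a [default_config()].
#' @return list: `per_sample` (tibble), `cluster_summary`, `model`.
#' @export
analyze_motility <- function(study, config = default_config()) {
  kin_all <- dplyr::bind_rows(study$kinematics, .id = "sample_id")
  cls <- classify_motility(kin_all, config$motility$motile_vcl_cut)
  kin_all$motility_class <- cls
  per_sample_mot <- kin_all |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(
      pct_motile = 100 * mean(.data$motility_class != "immotile"),
      pct_progressive = 100 * mean(.data$motility_class == "progressive"),
      .groups = "drop")
  motile <- kin_all[cls != "immotile", ]
  model <- cluster_subpopulations(motile, config$motility$stage1_k,
                                  config$motility$k_range, config$seed)
  summ <- summarize_subpopulations(model, motile, motile$sample_id)
  per_sample <- dplyr::left_join(per_sample_mot, summ$sample_percentages,
                                 by = "sample_id")
  list(per_sample = per_sample, cluster_summary = summ$cluster_summary,
       model = model)
}

#' Run the full study analysis
#'
#' End-to-end orchestration: generate (or accept) a study, gate and compute
#' per-sample statistics, run the motility subpopulation analysis, fit the
#' factorial mixed models for the chromatin variables, compute per-day
#' FDR-masked correlation matrices and Hoeffding-D variable clusterings, and
#' a pooled standardized PCA with observation clustering. Identical config
#' and seed give identical output.
#'
#' @param config a [default_config()]; `config$seed` drives generation and
#'   clustering.
#' @param study optional pre-generated [generate_study()] result; by default
#'   a study with `design` is generated.
#' @param design a [study_design()] used when `study` is NULL.
#' @param out_dir optional directory: per-sample statistics, model table and
#'   PCA outputs are written as CSV/JSON.
#' @return list of class `report_bundle`: `sample_table`, `qc_excluded`,
#'   `gating_log`, `motility`, `model_table`, `correlations` (per day),
#'   `variable_clusters` (per day), `pca`, `pca_clusters`, `provenance`.
#' @export
run_study_analysis <- function(config = default_config(),
                               study = NULL,
                               design = study_design(seed = config$seed),
                               out_dir = NULL) {
  if (is.null(study)) study <- generate_study(design)
  st <- build_sample_table(study, config)
  tab <- st$sample_table
  mot <- analyze_motility(study, config)
  tab <- dplyr::left_join(tab, mot$per_sample, by = "sample_id")
  models <- fit_factorial_mixed_models(tab, chromatin_variables())
  days <- unique(tab$day)
  correlations <- lapply(stats::setNames(days, days), function(d)
    correlation_matrix(tab[tab$day == d, ], chromatin_variables(),
                       config$multivariate$alpha))
  varclust <- lapply(stats::setNames(days, days), function(d)
    cluster_variables(tab[tab$day == d, ], chromatin_variables()))
  pca <- principal_components(tab, chromatin_variables())
  pca_clusters <- cluster_observations_on_pcs(pca,
                                              config$multivariate$n_pcs,
                                              config$multivariate$k_obs)
  provenance <- list(config_hash = rlang::hash(config), seed = config$seed,
                     package_version = as.character(utils::packageVersion("spermchrom")),
                     r_version = R.version.string,
                     n_samples = nrow(tab),
                     n_excluded = nrow(st$qc_excluded))
  bundle <- structure(list(sample_table = tab, qc_excluded = st$qc_excluded,
                           gating_log = st$gating_log, motility = mot,
                           model_table = models, correlations = correlations,
                           variable_clusters = varclust, pca = pca,
                           pca_clusters = pca_clusters,
                           provenance = provenance),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write the main tables of a report bundle
#'
#' @param bundle a [run_study_analysis()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$sample_table, file.path(dir, "sample_table.csv"))
  readr::write_csv(bundle$model_table, file.path(dir, "model_table.csv"))
  readr::write_csv(bundle$motility$cluster_summary,
                   file.path(dir, "motility_subpopulations.csv"))
  pca_tab <- tibble::tibble(
    variable = rep(bundle$pca$variables, 2),
    component = rep(c("PC1", "PC2"), each = length(bundle$pca$variables)),
    loading = c(bundle$pca$loadings[, 1], bundle$pca$loadings[, 2]),
    contribution = c(bundle$pca$contributions[, 1],
                     bundle$pca$contributions[, 2]))
  readr::write_csv(pca_tab, file.path(dir, "pca_loadings.csv"))
  for (d in names(bundle$correlations)) {
    co <- bundle$correlations[[d]]
    long <- tibble::as_tibble(as.data.frame(as.table(co$r)),
                              .name_repair = "minimal")
    names(long) <- c("var1", "var2", "r")
    long$p_adjusted <- as.vector(co$p_adjusted)
    long$significant <- as.vector(co$significant)
    readr::write_csv(long, file.path(dir, sprintf("correlations_%s.csv", d)))
  }
  jsonlite::write_json(
    list(provenance = bundle$provenance,
         qc_excluded = bundle$qc_excluded,
         gating = bundle$gating_log),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
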