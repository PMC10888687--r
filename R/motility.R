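#' Derive CASA kinematic records from raw velocities
#'
#' Computes the trajectory ratios and "dance" measures from the three
#' velocities: LIN = 100*VSL/VCL, STR = 100*VSL/VAP, WOB = 100*VAP/VCL,
#' DNC = VCL*ALH (um^2/s) and DNCm = DNC/VSL (um). A zero VSL gives
#' LIN = STR = 0 and an undefined (NA) DNCm, flagged rather than failing.
#'
#' @param vcl,vsl,vap curvilinear, straight-line and average-path velocities
#'   (um/s); `vcl` and `vap` must be positive, `vsl >= 0`.
#' @param alh amplitude of lateral head displacement (um).
#' @param bcf beat-cross frequency (Hz).
#' @return tibble with columns `vcl`, `vsl`, `vap`, `lin`, `str`, `wob`,
#'   `alh`, `bcf`, `dnc`, `dncm`.
#' @examples
#' derive_kinematics(100, 25, 50, 2, 10)  # lin 25, str 50, wob 50, dnc 200
#' @export
derive_kinematics <- function(vcl, vsl, vap, alh, bcf) {
  if (any(vcl <= 0) || any(vap <= 0))
    stop("vcl and vap must be positive")
  if (any(vsl < 0) || any(alh < 0) || any(bcf < 0))
    stop("vsl, alh and bcf must be non-negative")
  dnc <- vcl * alh
  tibble::tibble(
    vcl = vcl, vsl = vsl, vap = vap,
    lin = 100 * vsl / vcl,
    str = 100 * vsl / vap,
    wob = 100 * vap / vcl,
    alh = alh, bcf = bcf,
    dnc = dnc,
    dncm = ifelse(vsl > 0, dnc / vsl, NA_real_))
}

#' Classify per-cell motility
#'
#' Progressive cells satisfy VCL > 25 um/s and STR > 45%; motile
#' (non-progressive) cells reach the motile VCL cut (default 10 um/s);
#' the rest are immotile.
#'
#' @param kin a kinematic tibble from [derive_kinematics()].
#' @param motile_vcl_cut VCL threshold for motility, um/s.
#' @return factor with levels `immotile`, `nonprogressive`, `progressive`.
#' @export
classify_motility <- function(kin, motile_vcl_cut = 10) {
  out <- ifelse(kin$vcl > 25 & kin$str > 45, "progressive",
                ifelse(kin$vcl >= motile_vcl_cut, "nonprogressive",
                       "immotile"))
  factor(out, levels = c("immotile", "nonprogressive", "progressive"))
}

.KINEMATIC_FEATURES <- c("vcl", "vsl", "vap", "lin", "str", "wob", "alh", "bcf")
.KINEMATIC_ALL <- c(.KINEMATIC_FEATURES, "dnc", "dncm")

#' Two-stage motility subpopulation clustering
#'
#' Stage 1 compresses the pooled motile cells with k-means (`stage1_k`
#' groups) on z-scored kinematics (VCL, VSL, VAP, LIN, STR, WOB, ALH, BCF;
#' the derived dance measures are excluded to avoid double counting). Stage
#' 2 clusters the stage-1 centroids by Ward linkage and cuts the tree at the
#' k in `k_range` maximizing the centroid silhouette width. Cells inherit
#' the final label of their stage-1 group. Rows are internally sorted before
#' k-means so the result does not depend on input order.
#'
#' @param cells pooled kinematic tibble (motile cells); must carry a
#'   `sample_id` column if per-sample percentages are wanted downstream.
#' @param stage1_k number of stage-1 k-means groups (default 40).
#' @param k_range candidate final cluster counts (default 2:6).
#' @param seed integer seed for the k-means initialization.
#' @param features kinematic columns used for clustering.
#' @return object of class `subpop_model`: `stage1_centroids`, `final_k`,
#'   `final_centroids` (original scale), `labels` (per input row),
#'   `silhouette` (by candidate k), `features`, scaling constants.
#' @export
cluster_subpopulations <- function(cells, stage1_k = 40, k_range = 2:6,
                                   seed = 1L,
                                   features = .KINEMATIC_FEATURES) {
  stopifnot(all(features %in% names(cells)))
  x <- as.matrix(cells[, features])
  if (anyNA(x)) stop("kinematic columns must be complete")
  if (nrow(x) < stage1_k)
    stop("fewer cells than stage1_k")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance kinematic column: ",
         paste(features[sds == 0], collapse = ", "))
  mus <- colMeans(x)
  z <- scale(x, center = mus, scale = sds)
  ord <- do.call(order, as.data.frame(z))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  # stage 1 is a compression step: exhausting Hartigan-Wong's
  # Quick-TRANSfer budget on very large pooled inputs is benign, so that
  # specific warning is muffled
  km <- withCallingHandlers(
    stats::kmeans(z[ord, , drop = FALSE], centers = stage1_k,
                  iter.max = 100, nstart = 5),
    warning = function(w) {
      if (grepl("Quick-TRANSfer|did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  stage1_lab <- integer(nrow(z))
  stage1_lab[ord] <- km$cluster
  cen <- km$centers
  hc <- stats::hclust(stats::dist(cen), method = "ward.D2")
  k_range <- k_range[k_range >= 1 & k_range <= nrow(cen)]
  if (!length(k_range)) stop("no admissible k in k_range")
  sil <- vapply(k_range, function(k) {
    if (k < 2 || k == nrow(cen)) return(NA_real_)
    cl <- stats::cutree(hc, k)
    mean(cluster::silhouette(cl, stats::dist(cen))[, "sil_width"])
  }, numeric(1))
  final_k <- if (all(is.na(sil))) k_range[1] else k_range[which.max(sil)]
  cut <- stats::cutree(hc, final_k)
  labels <- cut[stage1_lab]
  final_centroids <- t(vapply(seq_len(final_k), function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(length(features))))
  colnames(final_centroids) <- features
  structure(list(stage1_centroids = cen, final_k = final_k,
                 final_centroids = final_centroids,
                 labels = unname(labels),
                 silhouette = stats::setNames(sil, k_range),
                 features = features, center = mus, scale = sds),
            class = "subpop_model")
}

#' Summarize motility subpopulations
#'
#' Produces the descriptive per-cluster summary (median +/- median absolute
#' deviation of all ten kinematic variables plus the overall percentage of
#' cells per cluster) and, when a design is supplied, the per-sample cluster
#' percentage table (rows sum to 100).
#'
#' @param model a fitted [cluster_subpopulations()] model.
#' @param cells the kinematic tibble the model was fitted on.
#' @param sample_id optional per-cell sample identifier for the per-sample
#'   percentage table.
#' @return list with `cluster_summary` (tidy: cluster, variable, median,
#'   mad, pct_overall) and `sample_percentages` (wide tibble, or NULL).
#' @export
summarize_subpopulations <- function(model, cells, sample_id = NULL) {
  stopifnot(inherits(model, "subpop_model"),
            length(model$labels) == nrow(cells))
  vars <- intersect(.KINEMATIC_ALL, names(cells))
  lab <- model$labels
  cluster_summary <- purrr::map_dfr(sort(unique(lab)), function(cl) {
    sub <- cells[lab == cl, vars, drop = FALSE]
    tibble::tibble(
      cluster = cl, variable = vars,
      median = vapply(sub, stats::median, numeric(1), na.rm = TRUE),
      mad = vapply(sub, stats::mad, numeric(1), na.rm = TRUE),
      pct_overall = 100 * sum(lab == cl) / length(lab))
  })
  sample_percentages <- NULL
  if (!is.null(sample_id)) {
    stopifnot(length(sample_id) == nrow(cells))
    tab <- table(sample_id, lab)
    pct <- 100 * prop.table(tab, margin = 1)
    sample_percentages <- tibble::as_tibble(as.data.frame.matrix(pct),
                                            rownames = "sample_id")
    names(sample_percentages)[-1] <-
      paste0("subpop_", names(sample_percentages)[-1])
  }
  list(cluster_summary = cluster_summary,
       sample_percentages = sample_percentages)
}
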