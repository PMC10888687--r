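#' Generate a complete synthetic boar study
#'
#' Simulates every cytometry event table (one per sample x assay, with the
#' mBBr untreated/DTT pair linked) and one CASA table per sample for the
#' full boars x ejaculates x days design. Boar and ejaculate Gaussian random
#' intercepts and the fixed storage-day shift are applied to each assay's
#' truth parameters on the transformed scale, and the per-sample theoretical
#' value of every downstream statistic is recorded in the `truth` table.
#' The same seed gives bit-identical output.
#'
#' @param design a [study_design()].
#' @param truths named list of [assay_truth()] objects as produced by
#'   [default_truths()]; must contain at most one truth per assay.
#' @return list of class `synthetic_study`: `design` (the design object),
#'   `samples` (design table), `events` (per sample: named list of event
#'   tibbles), `kinematics` (per sample), `truth` (tibble, one row per
#'   sample with all theoretical statistic values).
#' @export
generate_study <- function(design, truths = default_truths()) {
  stopifnot(inherits(design, "study_design"))
  assays <- vapply(truths, function(t) t$assay, character(1))
  if (anyDuplicated(assays)) stop("duplicate assay truths")
  need <- c("SCSA", "MBBR", "CMA3", "OXODG", "PHYS1", "PHYS2", "CASA")
  if (!all(need %in% assays))
    stop("missing assay truths: ", paste(setdiff(need, assays), collapse = ", "))
  truths <- truths[match(need, assays)]
  names(truths) <- need
  samples <- design_table(design)
  if (nrow(samples) == 0) stop("design yields zero samples")

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(design$seed)

  # random intercepts per boar and per ejaculate for every truth parameter
  boars <- unique(samples$boar)
  ejacs <- unique(samples$ejaculate)
  effects <- lapply(truths, function(tr) {
    nm <- names(tr$base)
    list(
      boar = matrix(stats::rnorm(length(boars) * length(nm)) *
                      rep(tr$boar_sd, each = length(boars)),
                    nrow = length(boars), dimnames = list(boars, nm)),
      ejac = matrix(stats::rnorm(length(ejacs) * length(nm)) *
                      rep(tr$ejaculate_sd, each = length(ejacs)),
                    nrow = length(ejacs), dimnames = list(ejacs, nm)))
  })
  seeds <- matrix(sample.int(.Machine$integer.max - 10L,
                             nrow(samples) * length(need)),
                  nrow = nrow(samples))

  events <- vector("list", nrow(samples))
  kinematics <- vector("list", nrow(samples))
  truth_rows <- vector("list", nrow(samples))
  names(events) <- names(kinematics) <- samples$sample_id
  n <- design$events_per_sample

  for (i in seq_len(nrow(samples))) {
    b <- samples$boar[i]; e <- samples$ejaculate[i]
    di <- match(samples$day[i], design$days) - 1L
    par <- lapply(need, function(a)
      realize_truth(truths[[a]], effects[[a]]$boar[b, ],
                    effects[[a]]$ejac[e, ], di))
    names(par) <- need

    scsa <- simulate_scsa_events(truths$SCSA, n, seeds[i, 1], par$SCSA)
    mbbr <- simulate_stain_pair_mbbr(truths$MBBR, n, seeds[i, 2], par$MBBR)
    cma3 <- simulate_cma3_events(truths$CMA3, n, seeds[i, 3], par$CMA3)
    oxodg <- simulate_oxodg_events(truths$OXODG, n, seeds[i, 4], par$OXODG)
    phys <- simulate_phys_panels(truths$PHYS1, truths$PHYS2, n, seeds[i, 5],
                                 par$PHYS1, par$PHYS2)
    comp <- casa_components_realized(par$CASA)
    kin <- simulate_casa_sample(comp, design$casa_cells_per_sample,
                                seeds[i, 7])
    events[[i]] <- list(scsa = scsa, mbbr_untreated = mbbr$untreated,
                        mbbr_dtt = mbbr$dtt, cma3 = cma3, oxodg = oxodg,
                        phys1 = phys$panel1, phys2 = phys$panel2)
    kinematics[[i]] <- kin
    truth_rows[[i]] <- tibble::as_tibble(as.list(c(
      attr(scsa, "truth"), attr(mbbr, "truth")[1:5], attr(cma3, "truth"),
      attr(oxodg, "truth"), attr(phys, "truth"),
      motile_fraction = 100 * par$CASA[["motile"]])))
  }

  truth <- dplyr::bind_cols(samples, dplyr::bind_rows(truth_rows))
  structure(list(design = design, samples = samples, events = events,
                 kinematics = kinematics, truth = truth, truths = truths),
            class = "synthetic_study")
}
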