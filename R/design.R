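#' Define a boar study design
#'
#' Describes the factorial layout emulated by the synthetic generator: a set
#' of boars, repeated ejaculates (AI doses) per boar, and two analysis days
#' per dose -- immediately after collection (`D0`) and after prolonged cooled
#' storage (`D11`). The two days of one ejaculate are aliquots of the same
#' dose, which is why the ejaculate is the random unit in the downstream
#' mixed models.
#'
#' @param boars number of boars (>= 1); default 36.
#' @param ejaculates_per_boar repeated doses per boar (>= 1); default 3.
#' @param days character vector of analysis-day labels; default `c("D0","D11")`.
#' @param events_per_sample cytometry events acquired per sample and assay
#'   (>= 1); default 5000, the acquisition floor used in practice.
#' @param casa_cells_per_sample tracked cells per CASA sample; default 500.
#' @param seed integer seed driving every stochastic stage of the generator.
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design(boars = 2, ejaculates_per_boar = 1)
#' nrow(design_table(d))  # 2 boars x 1 ejaculate x 2 days = 4 samples
#' @export
study_design <- function(boars = 36, ejaculates_per_boar = 3,
                         days = c("D0", "D11"),
                         events_per_sample = 5000,
                         casa_cells_per_sample = 500,
                         seed = 1L) {
  stopifnot(boars >= 1, ejaculates_per_boar >= 1, events_per_sample >= 1,
            casa_cells_per_sample >= 1, length(days) >= 1,
            !anyDuplicated(days))
  structure(list(boars = as.integer(boars),
                 ejaculates_per_boar = as.integer(ejaculates_per_boar),
                 days = as.character(days),
                 events_per_sample = as.integer(events_per_sample),
                 casa_cells_per_sample = as.integer(casa_cells_per_sample),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Expand a study design into its sample table
#'
#' @param design a [study_design()].
#' @return tibble with one row per sample: `sample_id`, `boar`, `ejaculate`,
#'   `day`. Total rows = boars x ejaculates x days.
#' @export
design_table <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- expand.grid(day = design$days,
                      ejaculate = seq_len(design$ejaculates_per_boar),
                      boar = seq_len(design$boars),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("B%02d_E%d_%s", grid$boar, grid$ejaculate, grid$day),
    boar = sprintf("B%02d", grid$boar),
    ejaculate = sprintf("B%02d_E%d", grid$boar, grid$ejaculate),
    day = grid$day
  )[order(grid$boar, grid$ejaculate, match(grid$day, design$days)), ]
}
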