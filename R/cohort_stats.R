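#' Per-slide sample metadata
#'
#' @param patient patient identifier.
#' @param volume_ml blood volume in mL (default 8).
#' @param total_cells total nucleated cells in the sample.
#' @param cells_plated nucleated cells plated on the analyzed slide(s)
#'   (<= `total_cells`).
#' @return An object of class `slide_meta`.
#' @export
slide_meta <- function(patient, volume_ml = 8, total_cells, cells_plated) {
  if (volume_ml <= 0) stop("volume_ml must be > 0")
  if (total_cells <= 0 || cells_plated <= 0) stop("cell counts must be > 0")
  if (cells_plated > total_cells) stop("cells_plated must be <= total_cells")
  structure(list(patient = patient, volume_ml = volume_ml,
                 total_cells = total_cells, cells_plated = cells_plated),
            class = "slide_meta")
}

#' Extrapolate analyzed-slide counts to events per mL of blood
#'
#' Only a fraction of the sample's nucleated cells is plated on the
#' analyzed slide(s); counts are scaled by the inverse plated fraction and
#' divided by the blood volume:
#' `count * (total_cells / cells_plated) / volume_ml`.
#'
#' @param count events counted on the analyzed slides.
#' @param meta a [slide_meta()].
#' @return Events per mL.
#' @export
per_ml <- function(count, meta) {
  stopifnot(inherits(meta, "slide_meta"))
  if (meta$cells_plated <= 0) stop("division error: zero plated cells")
  count * (meta$total_cells / meta$cells_plated) / meta$volume_ml
}

#' Summarize one patient's per-mL enumeration row
#'
#' Totals and fractions from the six per-mL phenotype counts. Whether
#' "total CTCs" includes in-contact (PIC) events is reported both ways
#' (`total_ctc_incl_pic`, `total_ctc_excl_pic`); the PIC fraction uses the
#' inclusive denominator. Fractions with a zero denominator are undefined
#' (`NA`), not 0.
#'
#' @param row list or one-row data.frame with `im_ctc`, `epi_ctc`,
#'   `pic_ctc`, `im_lev`, `epi_lev`, `pic_lev` (all per mL, >= 0).
#' @return data.frame with totals and fractions.
#' @export
summarize_patient <- function(row) {
  need <- c("im_ctc", "epi_ctc", "pic_ctc", "im_lev", "epi_lev", "pic_lev")
  if (!all(need %in% names(row))) {
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(row)), collapse = ", ")))
  }
  v <- lapply(need, function(nm) as.numeric(row[[nm]]))
  names(v) <- need
  if (any(unlist(v) < 0)) stop("counts must be >= 0")
  total_ctc <- v$im_ctc + v$epi_ctc + v$pic_ctc
  total_lev <- v$im_lev + v$epi_lev + v$pic_lev
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  data.frame(
    total_ctc_incl_pic = total_ctc,
    total_ctc_excl_pic = v$im_ctc + v$epi_ctc,
    total_lev_incl_pic = total_lev,
    total_lev_excl_pic = v$im_lev + v$epi_lev,
    pic_ctc_fraction = frac(v$pic_ctc, total_ctc),
    pic_lev_fraction = frac(v$pic_lev, total_lev),
    im_ctc_fraction = frac(v$im_ctc, v$im_ctc + v$epi_ctc),
    im_lev_fraction = frac(v$im_lev, v$im_lev + v$epi_lev))
}

#' Integer percentage, rounding half up
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @return `k / n * 100` rounded half-up to the nearest integer.
#' @export
percent_of <- function(k, n) {
  if (n <= 0) stop("denominator must be > 0")
  round_half_up(k / n * 100)
}

#' Cohort positivity summary
#'
#' Counts and integer percentages of patients positive for each event
#' category.
#'
#' @param patients data.frame with one row per patient and logical (or
#'   0/1) columns among `has_ctc`, `has_im_ctc`, `has_lev`, `has_im_lev`,
#'   `has_pic`.
#' @param denominators optional named list mapping a column to the
#'   denominator used for its percentage (e.g. im.CTC positivity among
#'   CTC-positive patients); defaults to all patients.
#' @return data.frame with `category`, `n_positive`, `n_total`, `percent`.
#' @export
summarize_cohort <- function(patients, denominators = list()) {
  if (nrow(patients) < 1L) stop("need >= 1 patient")
  cols <- intersect(c("has_ctc", "has_im_ctc", "has_lev", "has_im_lev",
                      "has_pic"), names(patients))
  do.call(rbind, lapply(cols, function(cl) {
    n_total <- denominators[[cl]] %||% nrow(patients)
    n_pos <- sum(as.logical(patients[[cl]]))
    data.frame(category = sub("^has_", "", cl), n_positive = n_pos,
               n_total = n_total, percent = percent_of(n_pos, n_total))
  }))
}

#' Bundled per-patient enumeration table
#'
#' Published per-mL enumeration of standalone and in-contact CTC and LEV
#' phenotypes for the eight LEV-evaluable patients of a 148-patient
#' metastatic breast cancer cohort, shipped as a plain-text fixture.
#'
#' @return data.frame with columns `patient`, `im_ctc`, `epi_ctc`,
#'   `pic_ctc`, `im_lev`, `epi_lev`, `pic_lev` (counts per mL).
#' @export
load_enumeration_table <- function() {
  f <- system.file("extdata", "cohort_enumeration_per_ml.csv",
                   package = "picscore", mustWork = TRUE)
  utils::read.csv(f)
}
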