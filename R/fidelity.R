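#' Previously published 25-gene reference selection for GSE9476
#'
#' Feature indices reported for the CuMiDa GSE9476 leukemia dataset in the
#' study that introduced this selection filter, kept for overlap reporting
#' by [fidelity_gse9476()]. Their index base (0 or 1) and column convention
#' are not documented, so overlap is reported under both bases and never
#' asserted.
#'
#' @format Integer vector of length 25.
#' @export
reference_selection_gse9476 <- c(
  5436L, 1756L, 9888L, 2784L, 8673L, 6863L, 5699L, 5294L, 3831L, 10839L,
  7616L, 9537L, 188L, 12159L, 2899L, 1951L, 18418L, 7538L, 4881L, 17796L,
  15603L, 4048L, 2539L, 1712L, 17618L)

#' Fidelity experiment on the CuMiDa GSE9476 leukemia dataset
#'
#' Optional, network-dependent experiment: applies the full pipeline to the
#' externally downloaded CuMiDa GSE9476 CSV (64 samples, 5 classes) with the
#' study's stated settings — 25 selected genes, a stratified 60/40 split,
#' 5-fold cross-validation, 100 LSTM epochs — and reports the resulting
#' metric table plus the overlap of the 25 selected gene indices with
#' [reference_selection_gse9476] under both 0- and 1-based interpretations.
#' Overlap is reported, not asserted: the published preprocessing and index
#' conventions are underdetermined. The CSV is not shipped; see
#' `inst/scripts/fetch_gse9476.R`.
#'
#' @param csv_path path to the CuMiDa `Leukemia_GSE9476.csv`.
#' @param out_dir optional directory for the full report set.
#' @param seed seed for the split and classifiers. Default 42.
#' @return Invisibly, a list with `summary` (metric table), `selected`
#'   (1-based indices), and `overlap` (counts under both index bases).
#' @export
fidelity_gse9476 <- function(csv_path, out_dir = NULL, seed = 42L) {
  if (!file.exists(csv_path)) {
    stop(sprintf(paste("GSE9476 CSV not found at '%s'. This experiment needs the",
                       "externally downloaded CuMiDa dataset; see",
                       "inst/scripts/fetch_gse9476.R"), csv_path), call. = FALSE)
  }
  em <- read_expression(csv_path, label_column = "type")
  res <- run_pipeline(em, k = 25L, seed = seed, kfold_k = 5L,
                      out_dir = out_dir)
  sel <- res$selection$selected
  overlap <- c(
    base1 = length(intersect(sel, reference_selection_gse9476)),
    base0 = length(intersect(sel - 1L, reference_selection_gse9476))
  )
  message("metric table:")
  print(res$summary)
  message(sprintf("selection overlap with the published reference list: %d (1-based) / %d (0-based) of 25",
                  overlap[["base1"]], overlap[["base0"]]))
  invisible(list(summary = res$summary, selected = sel, overlap = overlap))
}
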