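#' FMO-referenced effect size for flow cytometry
#'
#' Cohen's-d-style standardized difference between a complete stain and its
#' fluorescence-minus-one (FMO) control:
#' `(mean_full - mean_fmo) / sqrt((sd_full^2 + sd_fmo^2) / 2)`.
#' Referencing each marker to its own FMO control absorbs donor-to-donor
#' autofluorescence differences.
#'
#' @param data Data frame with columns `mean_full`, `sd_full`, `mean_fmo`,
#'   `sd_fmo` (one row per marker/donor).
#' @return The input as a tibble with an `effect_size` column appended.
#' @export
fmo_effect_size <- function(data) {
  data <- as_tibble(data)
  need <- c("mean_full", "sd_full", "mean_fmo", "sd_fmo")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  if (any(data$sd_full < 0 | data$sd_fmo < 0)) abort("SDs must be nonnegative.")
  denom <- sqrt((data$sd_full^2 + data$sd_fmo^2) / 2)
  if (any(denom == 0)) abort("Zero pooled SD: effect size undefined.")
  mutate(data, effect_size = (.data$mean_full - .data$mean_fmo) / denom)
}

#' Mitochondrial respiration metrics from an OCR trace
#'
#' Derives the standard extracellular-flux quantities from phase-summary
#' oxygen consumption rates (pmol O2/min): basal respiration
#' (`baseline - post_rot_aa`), maximal respiration
#' (`post_fccp - post_rot_aa`), proton leak
#' (`post_oligomycin - post_rot_aa`), and — as a derived convenience —
#' ATP-linked respiration (`basal - proton_leak`). All metrics are invariant
#' to a common offset (baseline correction).
#'
#' @param data Data frame with columns `baseline`, `post_oligomycin`,
#'   `post_fccp`, `post_rot_aa` (one row per sample/replicate).
#' @return The input as a tibble with `basal`, `maximal`, `proton_leak`,
#'   `atp_linked` appended.
#' @export
ocr_metrics <- function(data) {
  data <- as_tibble(data)
  need <- c("baseline", "post_oligomycin", "post_fccp", "post_rot_aa")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  mutate(data,
         basal = .data$baseline - .data$post_rot_aa,
         maximal = .data$post_fccp - .data$post_rot_aa,
         proton_leak = .data$post_oligomycin - .data$post_rot_aa,
         atp_linked = .data$basal - .data$proton_leak)
}

#' Summarise an OCR time series into phase values
#'
#' Collapses a per-cycle OCR trace (three measurement cycles per phase in
#' the standard injection protocol) into one value per phase, by cycle mean
#' (default) or last cycle.
#'
#' @param data Data frame with columns `sample`, `phase` (one of
#'   `baseline`, `post_oligomycin`, `post_fccp`, `post_rot_aa`) and `ocr`.
#' @param method `"mean"` or `"last"`.
#' @return One row per sample with the four phase columns, ready for
#'   [ocr_metrics()].
#' @export
ocr_phase_summary <- function(data, method = c("mean", "last")) {
  method <- match.arg(method)
  data <- as_tibble(data)
  phases <- c("baseline", "post_oligomycin", "post_fccp", "post_rot_aa")
  bad <- setdiff(unique(data$phase), phases)
  if (length(bad)) abort(paste0("Unknown phase(s): ", paste(bad, collapse = ", ")))
  data |>
    group_by(.data$sample, .data$phase) |>
    summarise(ocr = if (method == "mean") mean(.data$ocr) else
      .data$ocr[dplyr::n()], .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "ocr")
}
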