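## Spike-in normalization of ChIP-ddPCR copy-number tables.

#' Normalize ddPCR target copy numbers against a spike-in reference
#'
#' One sample's spike-in value (copies per microliter of the PCR
#' reaction) is chosen as the reference. Each sample's normalization
#' factor is `reference spike-in / sample spike-in`, and every target
#' copy number is multiplied by its sample's factor; the reference
#' sample's factor is 1, so it is unchanged. The choice of reference
#' rescales all outputs by one common constant — between-sample ratios do
#' not depend on it.
#'
#' @param samples A tibble in long format with columns `sample_id`,
#'   `spikein` (> 0), `target`, `copies` (>= 0); one row per sample x
#'   target.
#' @param reference_id Sample id to normalize against. Default: the
#'   first sample in the table (a message notes the choice).
#' @return The input with added columns `norm_factor` and `normalized`.
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = c("S1", "S2"), spikein = c(200, 100),
#'   target = "Tat_GRE", copies = c(80, 50)
#' )
#' spikein_normalize(tbl, reference_id = "S1")
#' @export
spikein_normalize <- function(samples, reference_id = NULL) {
  check_that(all(c("sample_id", "spikein", "target", "copies") %in%
                   names(samples)),
             "`samples` needs sample_id/spikein/target/copies columns")
  check_that(nrow(samples) > 0, "`samples` is empty")
  bad <- samples$spikein <= 0 | is.na(samples$spikein)
  if (any(bad)) {
    abort(paste0("non-positive spike-in for sample(s): ",
                 paste(unique(samples$sample_id[bad]), collapse = ", ")))
  }
  check_that(all(samples$copies >= 0), "`copies` must be >= 0")
  if (is.null(reference_id)) {
    reference_id <- samples$sample_id[1]
    rlang::inform(paste0("using first sample as spike-in reference: ",
                         reference_id))
  }
  check_that(reference_id %in% samples$sample_id,
             paste0("reference sample not found: ", reference_id))
  ref_spike <- unique(samples$spikein[samples$sample_id == reference_id])
  check_that(length(ref_spike) == 1,
             "reference sample has inconsistent spike-in values")
  out <- as_tibble(samples)
  out$norm_factor <- ref_spike / out$spikein
  out$normalized <- out$copies * out$norm_factor
  out
}

#' Read a wide ddPCR table and reshape to long format
#'
#' Expects a TSV with columns `sample_id`, `spikein`, then one column
#' per target.
#'
#' @param path Path to the TSV.
#' @return A long tibble suitable for [spikein_normalize()].
#' @export
read_ddpcr_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"
  ), progress = FALSE)
  check_that(all(c("sample_id", "spikein") %in% names(df)),
             "ddPCR table needs sample_id and spikein columns")
  tidyr::pivot_longer(df, cols = -c("sample_id", "spikein"),
                      names_to = "target", values_to = "copies")
}
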