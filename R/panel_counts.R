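#' Published off-target panel screening counts
#'
#' Per-target screening counts of a published 50-target safety panel:
#' gene symbol, target family, number of compounds screened, number of
#' actives, and the hit percent as printed in the source table (2 decimal
#' places, truncated). The printed hit percent reproduces
#' `100 * positives / screened` within 0.01 for every target, which makes
#' this table a compact end-to-end check of the hit-rate arithmetic in
#' [summarize_targets()].
#'
#' @return data.frame with columns `gene_symbol`, `target_family`,
#'   `screened`, `positives`, `hit_percent_printed`.
#' @export
#' @examples
#' pc <- offtarget_panel_counts()
#' max(abs(100 * pc$positives / pc$screened - pc$hit_percent_printed))
offtarget_panel_counts <- function() {
  utils::read.csv(
    system.file("extdata", "offtarget_panel_counts.csv",
                package = "offpanel", mustWork = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
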