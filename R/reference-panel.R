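#' Published reference marker panel
#'
#' The ten-species marker panel reported by a genome-scale E. coli
#' knock-out/overexpression lipidome screen under n-butanol stress, as a
#' reference for comparing panels selected on new data: per marker its
#' average, maximum and minimum percent contribution to the total MS
#' signal and the genetic constructs attaining the extremes. Summed over
#' the panel, the average contributions amount to 21.2% of the total
#' lipid-related signal.
#'
#' @return Tibble with `species`, `average_pct`, `max_pct`, `min_pct`,
#'   `max_construct`, `min_construct`.
#' @examples
#' round(sum(reference_marker_panel()$average_pct), 1) # 21.2
#' @export
reference_marker_panel <- function() {
  tibble(
    species = c("PE 34:1", "PE 32:1", "PE 36:2", "PG 35:0c1",
                "PG 31:0c1", "aPG 50:2", "aPE 49:0c1", "aPG 49:1c1",
                "PBut 33:0c1", "aPE 50:1"),
    average_pct = c(7.67, 5.75, 4.20, 2.60, 0.35, 0.26, 0.15, 0.10,
                    0.07, 0.07),
    max_pct = c(17.41, 24.82, 12.09, 10.47, 1.21, 2.94, 0.91, 1.00,
                2.99, 1.34),
    min_pct = c(0.72, 0.72, 0.84, 0.20, 0.05, 0.03, 0.01, 0.01, 0.00,
                0.00),
    max_construct = c("glpD (OV)", "cfa (KO)", "fabH (KO)", "glpR (KO)",
                      "fabH (OV)", "fadL (OV)", "aas (OV)", "pldA (OV)",
                      "clsB (OV)", "aas (OV)"),
    min_construct = c("fabH (OV)", "cfa (OV)", "fabH (OV)", "aas (OV)",
                      "fabH (KO)", "fabF (OV)", "cfa (KO)", "fabH (KO)",
                      "fadD (KO)", "clsA (OV)")
  )
}
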