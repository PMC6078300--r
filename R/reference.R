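#' Published reference summary statistics for feline hind-limb gait
#'
#' Bilateral mean, SD, maximum, minimum, and range of motion (degrees) of
#' hip, stifle, and tarsal joint angles in all three planes over the average
#' step cycle, as published for a representative healthy adult cat walking
#' overground, analyzed with a multiplane joint-coordinate-system model.
#' Useful as a plausibility reference for new data and for checking the
#' internal arithmetic of summary tables (`rom = max - min` up to print
#' rounding).
#'
#' @return Data frame with columns `side`, `joint`, `plane`, `mean`, `sd`,
#'   `max`, `min`, `rom`.
#' @export
reference_rom_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_rom_summary.csv",
                              package = "hindkin"),
                  stringsAsFactors = FALSE)
}
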