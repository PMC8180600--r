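#' Canonical simulation Q-matrix (30 items, 5 attributes)
#'
#' The standard 30 x 5 simulation design used throughout the package's
#' simulation study: ten single-attribute items (each attribute twice), ten
#' two-attribute items (every pair once), and ten three-attribute items
#' (every triple once). Also shipped as `inst/extdata/q_sim30.csv`.
#'
#' @return a [qmatrix()] with J = 30, K = 5.
#' @export
qmatrix_sim30 <- function() {
  rows <- c(
    "10000", "01000", "00100", "00010", "00001",
    "10000", "01000", "00100", "00010", "00001",
    "11000", "10100", "10010", "10001", "01100",
    "01010", "01001", "00110", "00101", "00011",
    "11100", "11010", "11001", "10110", "10101",
    "10011", "01110", "01101", "01011", "00111")
  qmatrix(string_to_pattern(rows),
          item_ids = paste0("I", seq_along(rows)),
          attribute_ids = paste0("A", 1:5))
}

#' Two-item / two-attribute toy Q-matrix
#'
#' Item 1 requires both attributes, item 2 requires attribute 2 only. Its
#' DINA ideal-response dataset and counted CPTs form the package's worked
#' example (attribute marginals 2/4, deterministic item rows).
#'
#' @return a [qmatrix()] with J = 2, K = 2.
#' @export
qmatrix_toy2 <- function() {
  qmatrix(rbind(c(1L, 1L), c(0L, 1L)),
          item_ids = c("Item1", "Item2"), attribute_ids = c("A1", "A2"))
}

#' Buoyancy-test Q-matrix (14 items, 7 attributes)
#'
#' Q-matrix of a 14-item physics test on the buoyancy concept with seven
#' attributes (buoyancy direction, force identification, density, displaced
#' volume, force-based calculation, Archimedes' principle, float/sink
#' judgement). Used to exercise hierarchy-constrained workflows.
#'
#' @return a [qmatrix()] with J = 14, K = 7.
#' @export
qmatrix_buoyancy <- function() {
  rows <- c(
    "1000000", "0100000", "0010000", "0001000", "0010001",
    "0010001", "1100100", "1100100", "0011000", "0011010",
    "1110101", "0011011", "1111010", "1111111")
  qmatrix(string_to_pattern(rows),
          item_ids = paste0("I", seq_along(rows)),
          attribute_ids = paste0("A", 1:7))
}

#' Synthetic buoyancy attribute hierarchy
#'
#' A plausible prerequisite DAG over the seven buoyancy attributes,
#' constructed for this package (SYNTHETIC -- it is a stand-in with the same
#' shape class as a published expert hierarchy that is not redistributable
#' here): understanding force identification requires knowing the buoyancy
#' direction; force-based calculation requires force identification;
#' displaced volume builds on density; Archimedes' principle builds on
#' displaced volume; the float/sink judgement requires both density and
#' Archimedes' principle. Also shipped as
#' `inst/extdata/hierarchy_buoyancy_synthetic.json`.
#'
#' @return a [hierarchy_dag()] over A1..A7.
#' @export
hierarchy_buoyancy_synthetic <- function() {
  hierarchy_dag(rbind(
    c("A1", "A2"),
    c("A2", "A5"),
    c("A3", "A4"),
    c("A4", "A6"),
    c("A3", "A7"),
    c("A6", "A7")),
    attributes = paste0("A", 1:7))
}
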