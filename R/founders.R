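#' Founder panel definitions
#'
#' Each mapping panel carries eight founders: seven panel-specific lines
#' (A1-A7 or B1-B7) plus one line, AB8, shared between the two panels.  AB8 is
#' the same founder genome in both panels but is tracked under a distinct
#' label per panel (`AB8_A`, `AB8_B`) because the two panels' haplotype
#' probabilities are independent.
#'
#' @param panel_id "A" or "B".
#' @return An object of class `founder_panel` with `panel_id` and `founders`
#'   (eight labels).
#' @export
founder_panel <- function(panel_id = c("A", "B")) {
  panel_id <- match.arg(panel_id)
  founders <- c(paste0(panel_id, 1:7), "AB8")
  structure(list(panel_id = panel_id, founders = founders),
            class = "founder_panel")
}

# the 16 dosage column labels, maternal (pA) first
founder_column_labels <- function() {
  c(paste0("pA_", c(paste0("A", 1:7), "AB8")),
    paste0("pB_", c(paste0("B", 1:7), "AB8")))
}

# 15 distinct founder genomes (AB8 shared), used for simulation truth
founder_truth_labels <- function() {
  c(paste0("A", 1:7), paste0("B", 1:7), "AB8")
}

# map the 16 dosage columns onto the 15 truth labels
truth_index_of_columns <- function() {
  match(c(paste0("A", 1:7), "AB8", paste0("B", 1:7), "AB8"),
        founder_truth_labels())
}
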