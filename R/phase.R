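#' Assign incubation phase to a day of the microcosm experiment
#'
#' The 8-day incubation is split by the observed cell-density dynamics into
#' an early phase (days 0-1, densities decreasing or barely increasing), a
#' middle phase (days 2-4, densities increasing) and a late phase (days 5-7,
#' densities saturated).
#'
#' @param day Integer vector of incubation days, each in 0..7.
#' @return Character vector of `"early"`, `"middle"` or `"late"`.
#' @export
#' @examples
#' assign_phase(0:7)
assign_phase <- function(day) {
  if (length(day) == 0L) return(character(0))
  if (any(!is.finite(day)) || any(day != floor(day))) {
    bt_stop("'day' must be integer-valued")
  }
  if (any(day < 0 | day > 7)) {
    bt_stop("'day' must be within 0..7; got ", paste(day[day < 0 | day > 7], collapse = ", "))
  }
  ifelse(day <= 1, "early", ifelse(day <= 4, "middle", "late"))
}

#' Valid microcosm treatments and replicate labels
#' @noRd
TREATMENTS <- c("control", "CIF", "HIF")
REPLICATES <- c("I", "II", "III")
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
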