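#' Element sets for fertigation mass-balance analysis
#'
#' The uptake / deviation analysis covers the ten elements assayed in both
#' solution and tissue: N, P, K, Ca, Mg, Fe, Mn, B, Cu and Zn. Supply recipes
#' may contain additional supply-only elements (e.g. Mo) which are accepted in
#' inputs but excluded from uptake analysis.
#'
#' @return `measured_elements()` and `supply_only_elements()` return character
#'   vectors of element symbols; `is_measured_element()` returns a logical
#'   vector.
#' @examples
#' measured_elements()
#' is_measured_element(c("N", "Mo"))
#' @export
measured_elements <- function() {
  c("N", "P", "K", "Ca", "Mg", "Fe", "Mn", "B", "Cu", "Zn")
}

#' @rdname measured_elements
#' @export
supply_only_elements <- function() "Mo"

#' @rdname measured_elements
#' @param element character vector of element symbols.
#' @export
is_measured_element <- function(element) {
  element %in% measured_elements()
}

#' Validate a vector of element symbols
#'
#' Checks symbols against the known (measured + supply-only) set and errors on
#' anything unrecognized. Used by readers and the simulator.
#'
#' @param element character vector of element symbols.
#' @param allow_supply_only accept supply-only elements such as Mo?
#' @return the input, invisibly, if valid.
#' @keywords internal
check_elements <- function(element, allow_supply_only = TRUE) {
  known <- measured_elements()
  if (allow_supply_only) known <- c(known, supply_only_elements())
  bad <- setdiff(unique(element), known)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown element symbol(s): ", paste(bad, collapse = ", "),
      ". Known symbols: ", paste(known, collapse = ", "), "."
    ))
  }
  invisible(element)
}
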