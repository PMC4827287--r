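`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular face area from a diameter
#'
#' @param diameter_mm Diameter in millimetres.
#' @return Area in mm^2 (so force in N divided by it gives stress in MPa).
#' @keywords internal
face_area_mm2 <- function(diameter_mm) {
  stopifnot(is.numeric(diameter_mm), diameter_mm > 0)
  pi * (diameter_mm / 2)^2
}

stop_quant <- function(msg, ..., class) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "chondroquant_error")))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_quant("`%s` must be a single positive number", name, class = "invalid_argument")
  invisible(x)
}
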