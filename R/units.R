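#' Unit conversion helpers
#'
#' Interfaces of this package use the units clinicians and experimentalists
#' report (mm, mL/min, beats per minute); everything internal is SI
#' (m, s, Pa, kg). These helpers convert explicitly at the boundaries.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
um_to_mm <- function(x) x * 1e-3

#' @rdname units
#' @export
m3s_to_ml_min <- function(x) x * 6e7

#' @rdname units
#' @export
ml_min_to_m3s <- function(x) x / 6e7

#' @rdname units
#' @export
bpm_to_hz <- function(x) x / 60

# internal: stop with a field-named validation error
abort_field <- function(field, msg) {
  stop(sprintf("invalid geometry field '%s': %s", field, msg), call. = FALSE)
}
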