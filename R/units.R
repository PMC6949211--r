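#' Unit conversion helpers
#'
#' Flowrates are carried in mL/s inside the package; clinical tables usually
#' print L/min.  `lmin_to_mls()` and `mls_to_lmin()` convert between the two.
#'
#' @param x numeric vector of flowrates.
#' @return numeric vector in the target unit.
#' @examples
#' lmin_to_mls(23.5)   # 391.67 mL/s
#' @export
lmin_to_mls <- function(x) x * 1000 / 60

#' @rdname lmin_to_mls
#' @export
mls_to_lmin <- function(x) x * 60 / 1000

# 1 cmH2O in Pa (conventional water column at 4 C, standard gravity)
CMH2O_PA <- 98.0665

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
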