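# Classed conditions so callers (and the command-line driver) can map
# failures to machine-readable categories: format, geometry, annotation,
# measurement, config, analysis.

ropStop <- function(category, ...) {
  msg <- paste0(...)
  stop(structure(class = c(paste0("ropzone_", category), "ropzone_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Error category of a ropzone condition
#'
#' @param e a condition object.
#' @return One of \code{"format"}, \code{"geometry"}, \code{"annotation"},
#'   \code{"measurement"}, \code{"config"}, \code{"analysis"}, or
#'   \code{"other"} for conditions not raised by this package.
#' @export
errorCategory <- function(e) {
  cls <- grep("^ropzone_(?!error)", class(e), value = TRUE, perl = TRUE)
  if (length(cls)) sub("^ropzone_", "", cls[1]) else "other"
}
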