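#' Transform an outcome to its analysis scale
#'
#' The change-over-time models operate on normalising transforms chosen per
#' outcome: identity for d-prime and mood totals, square root for daily
#' step counts, natural log for mean heart rate. Domain violations name the
#' offending record.
#'
#' @param values numeric vector.
#' @param transform `"identity"`, `"log"`, or `"sqrt"`.
#' @return transformed values.
#' @export
transform_outcome <- function(values,
                              transform = c("identity", "log", "sqrt")) {
  transform <- match.arg(transform)
  ok <- !is.na(values)
  if (transform == "log" && any(values[ok] <= 0)) {
    stop("log transform requires strictly positive values; offending record(s): ",
         paste(head(which(ok & values <= 0), 5), collapse = ", "),
         call. = FALSE)
  }
  if (transform == "sqrt" && any(values[ok] < 0)) {
    stop("sqrt transform requires non-negative values; offending record(s): ",
         paste(head(which(ok & values < 0), 5), collapse = ", "),
         call. = FALSE)
  }
  switch(transform,
         identity = values,
         log = log(values),
         sqrt = sqrt(values))
}

#' Invert an outcome transform (for reporting on the raw scale)
#'
#' @param values transformed values.
#' @param transform the transform that produced them.
#' @return values on the original scale.
#' @export
inverse_transform_outcome <- function(values,
                                      transform = c("identity", "log", "sqrt")) {
  transform <- match.arg(transform)
  switch(transform,
         identity = values,
         log = exp(values),
         sqrt = values^2)
}

default_transform <- function(outcome) {
  switch(outcome,
         dprime = "identity", mood = "identity",
         steps = "sqrt", heart_rate = "log")
}

default_covariance <- function(outcome) {
  switch(outcome,
         dprime = "car1_continuous_time", mood = "car1_continuous_time",
         steps = "ar1_daily", heart_rate = "ar1_daily")
}
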