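#' A relaxation dispersion (NMRD) profile
#'
#' Container for a measured or synthetic 1H spin-lattice relaxation
#' dispersion curve: Larmor frequencies (MHz), relaxation rates R1 (s^-1),
#' optional per-point uncertainties, and free-form metadata (sample label,
#' temperature, generator settings).
#'
#' @param frequencies 1H Larmor frequencies in MHz, strictly increasing,
#'   positive
#' @param rates R1 values in s^-1, positive, same length
#' @param uncertainties optional per-point standard deviations (s^-1)
#' @param metadata named list of free-form metadata
#' @return object of class `relaxation_profile`
#' @export
relaxation_profile <- function(frequencies, rates, uncertainties = NULL,
                               metadata = list()) {
  frequencies <- as.numeric(frequencies)
  rates <- as.numeric(rates)
  if (length(frequencies) != length(rates))
    stop("frequencies and rates must have equal length", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be positive and finite (MHz)", call. = FALSE)
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be positive and finite (s^-1)", call. = FALSE)
  if (!is.null(uncertainties)) {
    uncertainties <- as.numeric(uncertainties)
    if (length(uncertainties) != length(rates) || any(uncertainties <= 0))
      stop("uncertainties must be positive and match the rates", call. = FALSE)
  }
  structure(list(frequencies = frequencies, rates = rates,
                 uncertainties = uncertainties, metadata = metadata),
            class = "relaxation_profile")
}

#' @export
print.relaxation_profile <- function(x, ...) {
  lab <- x$metadata$sample %||% "unnamed"
  cat(sprintf(
    "<relaxation profile> '%s': %d points, %.4g-%.4g MHz, R1 %.4g-%.4g s^-1\n",
    lab, length(x$frequencies), min(x$frequencies), max(x$frequencies),
    min(x$rates), max(x$rates)))
  invisible(x)
}

#' @export
as.data.frame.relaxation_profile <- function(x, ...) {
  d <- data.frame(frequency_MHz = x$frequencies, R1_per_s = x$rates)
  if (!is.null(x$uncertainties)) d$sigma_per_s <- x$uncertainties
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
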