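#' Photon-counting decay histogram
#'
#' Container for a TCSPC decay: photon counts on a uniform nanosecond time
#' grid. The grid must be strictly increasing and uniform (relative spacing
#' tolerance 1e-9) with at least 64 channels; counts are non-negative.
#'
#' @param times numeric vector, channel centres in ns.
#' @param counts non-negative photon counts, same length as `times`.
#' @return An object of class `"decay_trace"`: a list with elements `times`,
#'   `counts` and `channel_width` (ns per bin).
#' @export
decay_trace <- function(times, counts) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop("`times` and `counts` must have the same length", call. = FALSE)
  if (length(times) < 64L)
    stop("a decay trace needs at least 64 channels", call. = FALSE)
  if (anyNA(times) || anyNA(counts))
    stop("missing values in decay trace", call. = FALSE)
  if (any(counts < 0))
    stop("photon counts must be non-negative", call. = FALSE)
  dt <- check_uniform_grid(times)
  structure(list(times = times, counts = counts, channel_width = dt),
            class = "decay_trace")
}

#' Instrument response function
#'
#' The measured temporal profile of the excitation/detection chain, on the
#' same uniform-grid contract as the decay traces it is paired with. The
#' stored profile keeps its raw scale; it is normalised to unit sum
#' internally wherever it enters a convolution.
#'
#' @param times numeric vector, channel centres in ns.
#' @param counts non-negative real intensities with positive total.
#' @return An object of class `"instrument_response"` with elements `times`,
#'   `counts` and `channel_width`.
#' @export
instrument_response <- function(times, counts) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop("`times` and `counts` must have the same length", call. = FALSE)
  if (anyNA(times) || anyNA(counts))
    stop("missing values in instrument response", call. = FALSE)
  if (any(counts < 0))
    stop("instrument response intensities must be non-negative", call. = FALSE)
  if (sum(counts) <= 0)
    stop("instrument response has zero total intensity", call. = FALSE)
  dt <- check_uniform_grid(times)
  structure(list(times = times, counts = counts, channel_width = dt),
            class = "instrument_response")
}

# Returns the common spacing or stops if the grid is not strictly
# increasing and uniform within 1e-9 relative tolerance.
check_uniform_grid <- function(times) {
  d <- diff(times)
  if (any(d <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  dt <- d[1L]
  if (any(abs(d - dt) > 1e-9 * dt))
    stop("time grid must be uniform (relative tolerance 1e-9)", call. = FALSE)
  dt
}

#' @export
print.decay_trace <- function(x, ...) {
  cat("TCSPC decay trace\n")
  cat(sprintf("  %d channels x %.5g ns (%.5g-%.5g ns)\n",
              length(x$times), x$channel_width, x$times[1L],
              x$times[length(x$times)]))
  cat(sprintf("  total photons: %.4g, peak counts: %.4g\n",
              sum(x$counts), max(x$counts)))
  invisible(x)
}

#' @export
print.instrument_response <- function(x, ...) {
  cat("Instrument response function\n")
  cat(sprintf("  %d channels x %.5g ns, peak at %.4g ns\n",
              length(x$times), x$channel_width,
              x$times[which.max(x$counts)]))
  invisible(x)
}
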