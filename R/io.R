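#' Read a two-column TCSPC decay file
#'
#' Parses the deposited plain-text dialect: tab-delimited rows where the
#' first column is time (ns) and the second is photon counts, with optional
#' comment lines starting with `#`. Malformed rows are reported with their
#' line number; non-uniform grids are rejected.
#'
#' @param path file path.
#' @return A [decay_trace()].
#' @export
read_decay_file <- function(path) {
  tab <- parse_two_column(path)
  decay_trace(tab$time, tab$value)
}

#' Read an instrument response file
#'
#' Same two-column tab-delimited dialect as [read_decay_file()], but
#' intensities may be non-integer.
#'
#' @param path file path.
#' @return An [instrument_response()].
#' @export
read_irf_file <- function(path) {
  tab <- parse_two_column(path)
  instrument_response(tab$time, tab$value)
}

parse_two_column <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[idx]), "\t|\\s+")
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop(sprintf("parse error in %s at line %d: expected 2 columns, found %d",
                 path, idx[which(nf != 2L)[1L]], nf[nf != 2L][1L]),
         call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop(sprintf("parse error in %s at line %d: non-numeric field",
                 path, idx[bad]), call. = FALSE)
  }
  list(time = m[, 1L], value = m[, 2L])
}

#' Write a decay trace or instrument response as two-column text
#'
#' @param x a [decay_trace()] or [instrument_response()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_decay_file <- function(x, path) {
  stopifnot(inherits(x, c("decay_trace", "instrument_response")))
  writeLines(paste(format(x$times, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   format(x$counts, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

# sniff comma vs tab from the header line
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' Read an anisotropy titration table
#'
#' Headered delimited text (tab or comma) with columns `conc_nM` plus
#' either `anisotropy` or `i_par` and `i_perp`, and an optional
#' `replicate` column.
#'
#' @param path file path.
#' @return Data frame suitable for [fit_titration()].
#' @export
read_titration_table <- function(path) {
  d <- read_delim_auto(path)
  if (!"conc_nM" %in% names(d) ||
      !("anisotropy" %in% names(d) ||
        all(c("i_par", "i_perp") %in% names(d))))
    stop("titration table needs `conc_nM` and `anisotropy` (or `i_par` + ",
         "`i_perp`) columns", call. = FALSE)
  d
}

#' Write an anisotropy titration table
#'
#' @param data titration data frame.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(data, path) {
  utils::write.table(data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a gel lane band table
#'
#' Headered delimited text with columns `lane_id`, `band_label`, `signal`.
#'
#' @param path file path.
#' @return Named list (one element per lane, in file order) of named
#'   band-signal vectors.
#' @export
read_lane_table <- function(path) {
  d <- read_delim_auto(path)
  if (!all(c("lane_id", "band_label", "signal") %in% names(d)))
    stop("lane table needs `lane_id`, `band_label`, `signal` columns",
         call. = FALSE)
  lanes <- split(d, factor(d$lane_id, levels = unique(d$lane_id)))
  lapply(lanes, function(l) stats::setNames(l$signal, l$band_label))
}

#' Write a gel lane band table
#'
#' @param lanes named list of named band-signal vectors.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_lane_table <- function(lanes, path) {
  d <- do.call(rbind, lapply(names(lanes), function(id)
    data.frame(lane_id = id, band_label = names(lanes[[id]]),
               signal = unname(lanes[[id]]))))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kinetics time-series table
#'
#' Headered delimited text with columns `replicate`, `time_min`,
#' `fraction`.
#'
#' @param path file path.
#' @return Long data frame suitable for [aggregate_series()].
#' @export
read_series_table <- function(path) {
  d <- read_delim_auto(path)
  if (!all(c("replicate", "time_min", "fraction") %in% names(d)))
    stop("series table needs `replicate`, `time_min`, `fraction` columns",
         call. = FALSE)
  d
}

#' Write a kinetics time-series table
#'
#' @param series long data frame (`replicate`, `time_min`, `fraction`).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Structured key-value report for a fitted model
#'
#' Serialises a decay, two-step, or binding fit as `key<TAB>value` lines
#' mirroring the per-component fit tables of a lifetime analysis (component,
#' lifetime/centre, fwhm, amplitude, fraction, held flag, reduced
#' chi-square), so results are both human- and machine-readable.
#'
#' @param fit a `"decay_fit"`, `"two_step_fit"`, or `"binding_fit"`.
#' @param path optional destination file; when `NULL` the lines are
#'   returned only.
#' @return Character vector of report lines, invisibly when written.
#' @export
fit_report <- function(fit, path = NULL) {
  lines <- if (inherits(fit, "two_step_fit")) {
    c(paste0("control.", fit_report(fit$control)),
      paste0("sample.", fit_report(fit$sample)))
  } else if (inherits(fit, "decay_fit")) {
    m <- fit$model
    c(kv("discrete.lifetime_ns", m$tau_disc),
      kv("discrete.alpha", m$alpha_disc),
      kv("discrete.fraction", fit$fractions[["discrete"]]),
      kv("discrete.held", "tau_disc" %in% fit$fixed),
      kv("gaussian.center_ns", m$tau_g),
      kv("gaussian.fwhm_ns", m$fwhm_g),
      kv("gaussian.alpha", m$alpha_g),
      kv("gaussian.fraction", fit$fractions[["gaussian"]]),
      if (m$alpha_nuis > 0)
        kv("nuisance.photon_share",
           intensity_fractions(m)[["nuisance"]]),
      kv("baseline", m$baseline),
      kv("reduced_chi_square", fit$reduced_chi_square),
      kv("converged", fit$converged))
  } else if (inherits(fit, "binding_fit")) {
    p <- fit$params
    c(kv("kd_nM", p$kd), kv("hill_n", p$n), kv("hill_held", fit$held_n),
      kv("r_free", p$r_free), kv("r_bound", p$r_bound),
      kv("labeled_total_nM", fit$l_total),
      kv("residual_sum", fit$residual_sum),
      if (!is.null(fit$ci))
        unlist(lapply(rownames(fit$ci), function(nm)
          c(kv(paste0(nm, ".ci_lower"), fit$ci[nm, "lower"]),
            kv(paste0(nm, ".ci_upper"), fit$ci[nm, "upper"])))))
  } else {
    stop("unsupported fit object", call. = FALSE)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

kv <- function(key, value) {
  paste0(key, "\t", format(value, digits = 10, scientific = FALSE,
                           trim = TRUE))
}
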