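#' A stopped-flow fluorescence trace
#'
#' One relaxation record: a time series of fluorescence after an osmotic
#' shock, with the assay temperature and a strain/condition label.
#'
#' @param times numeric vector of times (s), strictly increasing, length >= 10
#' @param fluorescence numeric vector (a.u.), same length as `times`
#' @param temperature assay temperature (K)
#' @param label strain/condition identifier
#' @return an object of class `aq_trace`
#' @export
aq_trace <- function(times, fluorescence, temperature = 296.15,
                     label = "trace") {
  if (length(times) != length(fluorescence))
    stop("'times' and 'fluorescence' must have equal length")
  if (length(times) < 10) stop("a trace needs at least 10 points")
  if (any(!is.finite(times)) || any(!is.finite(fluorescence)))
    stop("trace values must be finite")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  stopifnot(is.finite(temperature), temperature > 0)
  structure(list(times = as.numeric(times),
                 fluorescence = as.numeric(fluorescence),
                 temperature = temperature,
                 label = as.character(label)),
            class = "aq_trace")
}

#' @export
print.aq_trace <- function(x, ...) {
  cat(sprintf("Stopped-flow trace '%s': %d points over %.3g s at %.2f K\n",
              x$label, length(x$times), max(x$times) - min(x$times),
              x$temperature))
  invisible(x)
}

#' Write / read a trace as CSV with a JSON metadata sidecar
#'
#' The CSV holds columns `time_s` and `fluorescence_au`; the sidecar
#' (`<path>.json`) holds `temperature_K`, `strain` and any extra metadata.
#'
#' @param trace an [aq_trace()] object
#' @param path CSV file path
#' @param meta optional named list of extra metadata for the sidecar
#' @return `path`, invisibly (for `write_trace`); an `aq_trace` (for
#'   `read_trace`)
#' @export
write_trace <- function(trace, path, meta = list()) {
  utils::write.csv(data.frame(time_s = trace$times,
                              fluorescence_au = trace$fluorescence),
                   path, row.names = FALSE)
  side <- c(list(temperature_K = trace$temperature, strain = trace$label),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "fluorescence_au") %in% names(d)))
    stop("trace CSV must have columns 'time_s' and 'fluorescence_au'")
  side_path <- paste0(path, ".json")
  temperature <- 296.15
  label <- sub("\\.csv$", "", basename(path))
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$temperature_K)) temperature <- side$temperature_K
    if (!is.null(side$strain)) label <- side$strain
  }
  aq_trace(d$time_s, d$fluorescence_au, temperature = temperature,
           label = label)
}
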