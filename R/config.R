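#' DSP specifications from JSON
#'
#' Reads stage parameters from a JSON object with coefficients as raw Q15
#' integers, the exchange format of the command-line tool:
#' `{"b": [...], "a": [...]}` for a filter, `{"h": [...], "D": n}` for a
#' polyphase decimator, `{"cos_w0": x, "N": n}` for a Goertzel detector
#' and `{"L": n, "H": n}` for a sliding window.
#'
#' @param path JSON file path (or a JSON string).
#' @return the corresponding specification object.
#' @export
filter_spec_from_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  filter_spec(b = j$b, a = j$a)
}

#' @rdname filter_spec_from_json
#' @export
polyphase_spec_from_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  polyphase_spec(h = j$h, D = j$D)
}

#' @rdname filter_spec_from_json
#' @export
goertzel_spec_from_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  goertzel_spec(cos_w0 = j$cos_w0, N = j$N,
                mode = if (is.null(j$mode)) "float" else j$mode)
}

#' @rdname filter_spec_from_json
#' @export
block_spec_from_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  block_spec(L = j$L, H = j$H)
}

#' Write an event log as a JSON report
#'
#' @param log an `event_log` from [run_pipeline()].
#' @param path output file.
#' @export
write_event_log_json <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}
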