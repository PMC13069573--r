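# Internal error helpers: validation errors (bad data) vs format errors
# (unparseable files) get distinct classes so callers and the CLI can map
# them to exit reasons.

abort_validation <- function(msg) {
  rlang::abort(msg, class = "nevar_validation_error")
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "nevar_format_error")
}

abort_fit <- function(msg) {
  rlang::abort(msg, class = "nevar_fit_error")
}

#' Duplication-mode codes
#'
#' The five duplication-mode codes accepted in paralog tables. All non-WGD
#' modes (tandem, proximal, transposed, dispersed) constitute small-scale
#' duplication (SSD).
#' @return Character vector of mode codes.
#' @export
paralog_modes <- function() {
  c("wgd", "tandem", "proximal", "transposed", "dispersed")
}

#' @rdname paralog_modes
#' @export
ssd_modes <- function() {
  setdiff(paralog_modes(), "wgd")
}

# Require columns, with a format error naming what is missing.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
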