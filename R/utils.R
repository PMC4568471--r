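#' @keywords internal
"_PACKAGE"

## NULL-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- stats::qlogis
invlogit <- stats::plogis

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Distinct pipeline components draw from independent, reproducible random
#' streams keyed off one master seed. The derived seed always fits in a
#' 32-bit signed integer.
#'
#' @param master master seed (integer).
#' @param offset component offset (small integer, one per stream).
#' @return an integer seed.
#' @export
derive_seed <- function(master, offset = 0L) {
  s <- (as.double(master) %% 2147483647) + 1
  s <- (s * 48271 + as.double(offset) * 7919) %% 2147483647
  as.integer(s)
}

stop_repsen <- function(..., class = "repsen_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_month <- function(month) {
  if (any(is.na(month)) || !all(month %in% 1:12)) {
    stop_repsen("`month` must be an integer in 1..12", class = "repsen_invalid_month")
  }
  as.integer(month)
}
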