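# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' All user-facing failures raise a condition inheriting from `"qus_error"`
#' plus a specific class (`"qus_geometry_error"`, `"qus_metadata_error"`, ...)
#' so callers and tests can discriminate failure modes.
#' @noRd
qus_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "qus_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a reproducible child seed from a root seed and a string key
#'
#' A single root seed drives a whole simulated study; per-image and per-stage
#' streams are derived by hashing the key so streams are independent yet
#' reproducible. Result is a valid 32-bit integer seed.
#' @noRd
derive_seed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((abs(root) + h) %% 2147483647)
}

match_view <- function(view) {
  if (!is.character(view) || length(view) != 1L ||
      !view %in% c("transverse", "longitudinal")) {
    qus_stop("`view` must be \"transverse\" or \"longitudinal\"", "qus_usage_error")
  }
  view
}

match_label <- function(label, allow_unknown = TRUE) {
  ok <- c("pos", "neg", if (allow_unknown) "unknown")
  if (!is.character(label) || length(label) != 1L || !label %in% ok) {
    qus_stop(sprintf("label must be one of %s", paste(ok, collapse = ", ")),
             "qus_usage_error")
  }
  label
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
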