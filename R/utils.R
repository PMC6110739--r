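#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# condition helpers: every user-facing failure carries a survmeta_* class so
# callers (and the CLI) can branch on it
stop_survmeta <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "survmeta_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_survmeta <- function(msg, class) {
  warning(structure(
    class = c(class, "survmeta_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# reverse cumulative sum: out[i] = sum(x[i:n])
revcumsum <- function(x) {
  if (length(x) == 0L) return(x)
  rev(cumsum(rev(x)))
}

# cheap stable content hash (31-ary polynomial over the serialized object,
# mod a Mersenne prime) used for dataset provenance; not cryptographic
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

trim <- function(x) trimws(as.character(x))
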