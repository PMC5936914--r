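#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a stage label.
# Kept below 2^31 so it is a valid R integer seed.
child_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}
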