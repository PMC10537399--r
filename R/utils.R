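`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar > 0 check with a readable message
check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}
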