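#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: mixes a master seed with index words so
# that replicate arms get independent, reproducible streams.  Arithmetic is
# exact in doubles (products stay far below 2^53) and results stay < 2^31.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Trapezoidal integration on an ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Clip a numeric vector into [lo, hi]; warn via `what` if clipping occurred.
clip_range <- function(x, lo, hi, what = NULL) {
  out <- pmin(pmax(x, lo), hi)
  if (!is.null(what) && any(out != x, na.rm = TRUE)) {
    warning(sprintf("%s outside [%g, %g]; clipped", what, lo, hi), call. = FALSE)
  }
  out
}

stop_cyclekin <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cyclekin_error")))
}
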