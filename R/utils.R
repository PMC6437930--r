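#' Canonical key for a marker combination
#'
#' Combination columns are addressed by a sorted, `+`-joined key so that
#' `c("TIM-3","CD3")` and `c("CD3","TIM-3")` name the same quantity.
#'
#' @param markers character vector of marker names
#' @return a single string, e.g. `"CD3+TIM-3"`
#' @export
combo_key <- function(markers) {
  paste(sort(unique(as.character(markers))), collapse = "+")
}

#' Split a combination key back into marker names
#' @param key a key produced by [combo_key()]
#' @return character vector of markers
#' @export
split_key <- function(key) {
  strsplit(key, "+", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under an explicit seed without touching global RNG state;
# seed = NULL runs in the ambient RNG stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# truncated-normal draw by rejection; bounds are hard limits
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- min(max(mean, lower), upper)
  out
}
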