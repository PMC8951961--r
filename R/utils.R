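`%||%` <- function(a, b) if (is.null(a)) b else a

# Scores are multiples of 0.5; comparisons go through integer half-units so
# equality and threshold tests are exact.
half_units <- function(x) as.integer(round(x * 2))

is_half_step <- function(x) {
  is.finite(x) & abs(x * 2 - round(x * 2)) < 1e-9
}

pts_ge <- function(x, t) half_units(x) >= half_units(t)

# "8.5", never "8.50"; "2", never "2.0"
fmt_pts <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, drop0trailing = TRUE,
                               scientific = FALSE), character(1))
}
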