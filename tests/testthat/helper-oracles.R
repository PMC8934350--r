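# Independent quadrature oracle for the log Gaussian tail.
# erfc(z) = (2/sqrt(pi)) * Int_z^Inf exp(-u^2) du; substituting u = z + s
# factors out exp(-z^2) so the integrand never underflows:
#   ln erfc(z) = ln(2/sqrt(pi)) - z^2 + ln Int_0^Inf exp(-2 z s - s^2) ds
ln_erfc_quadrature <- function(z) {
  vapply(z, function(zi) {
    tail <- integrate(function(s) exp(-2 * zi * s - s^2), 0, Inf,
                      rel.tol = 1e-12)$value
    log(2 / sqrt(pi)) - zi^2 + log(tail)
  }, numeric(1))
}

# moment-based shape statistics (population versions)
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
sample_excess_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

# write a tissue table literal to a temp file ("," separators become tabs)
write_table_file <- function(lines, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  writeLines(gsub(", ", sep, lines, fixed = TRUE), path)
  path
}
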