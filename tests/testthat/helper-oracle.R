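# Independent high-precision tail-probability oracle: adaptive quadrature
# of the density, a different computational path from the closed-form
# incomplete-beta/gamma tail calls the implementation uses.
oracle_p <- function(family, stat, df1 = NA, df2 = NA) {
  up <- function(dens, q) {
    stats::integrate(dens, q, Inf, rel.tol = 1e-12, abs.tol = 1e-14,
                     subdivisions = 1000L)$value
  }
  switch(family,
    t = 2 * up(function(x) stats::dt(x, df2), abs(stat)),
    r = {
      tv <- stat * sqrt(df2 / (1 - stat^2))
      2 * up(function(x) stats::dt(x, df2), abs(tv))
    },
    F = up(function(x) stats::df(x, df1, df2), stat),
    chi2 = up(function(x) stats::dchisq(x, df1), stat),
    Z = 2 * up(stats::dnorm, abs(stat))
  )
}

# write a small fixture file and return its path
write_fixture <- function(text, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(text, f, useBytes = TRUE)
  f
}
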