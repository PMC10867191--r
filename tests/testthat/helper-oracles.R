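## Fixtures and independent oracles shared across the test files.

## quick spectra object from a function of wavelength
fun_spectrum <- function(f, wl = 300:700, label = "s") {
  spectra(wl, matrix(f(wl), ncol = 1, dimnames = list(NULL, label)))
}

flat_spectrum <- function(value, wl = 300:700, label = "flat") {
  fun_spectrum(function(w) rep(value, length(w)), wl, label)
}

## random smooth flower-like reflectance curves (for property tests)
random_flower_spectra <- function(n, wl = 300:700) {
  refl <- vapply(seq_len(n), function(i) {
    base <- runif(1, 0.02, 0.6)
    step <- runif(1, 0, 0.6) * plogis((wl - runif(1, 400, 650)) / 20)
    band <- runif(1, 0, 0.5) * exp(-((wl - runif(1, 320, 680)) /
                                       runif(1, 20, 80))^2)
    pmin(base + step + band, 1.2)
  }, numeric(length(wl)))
  colnames(refl) <- sprintf("r%02d", seq_len(n))
  spectra(wl, refl)
}

## independently coded one-shot bee-vision implementation: same model
## definition, separate code path (pracma quadrature, direct formulas)
oracle_signals <- function(x, curves) {
  sapply(seq_len(ncol(x$refl)), function(j) {
    r <- x$refl[, j]
    P <- sapply(1:3, function(i)
      pracma::trapz(curves$wl, r * curves$illuminant * curves$S[, i]) /
        pracma::trapz(curves$wl,
                      curves$background * curves$illuminant * curves$S[, i]))
    E <- P / (1 + P)
    xx <- sqrt(3) / 2 * (E[3] - E[1])
    yy <- E[2] - (E[1] + E[3]) / 2
    c(x = xx, y = yy, cc = sqrt(xx^2 + yy^2), gc = abs(0.5 - E[3]))
  })
}

## direct-matrix GLS oracle: beta = (X' V^-1 X)^-1 X' V^-1 y
oracle_gls <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  se <- sqrt(diag(solve(XtVi %*% X)) * rss / (length(y) - ncol(X)))
  list(beta = drop(beta), se = se)
}

## small fixed newick strings written to temp files
write_newick <- function(txt) {
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  f
}
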