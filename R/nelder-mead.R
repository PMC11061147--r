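# Nelder-Mead simplex minimizer with explicit control over the initial
# simplex and a dual stopping rule (cost spread and simplex size), which
# stats::optim does not expose.  Standard coefficients: reflection 1,
# expansion 2, contraction 0.5, shrink 0.5.

.nelderMead <- function(fn, x0, step, reltol = 1e-10, stol = 1e-10,
                        abstol = -Inf, maxeval = 20000L) {
  n <- length(x0)
  S <- matrix(rep(x0, n + 1L), nrow = n + 1L, byrow = TRUE)
  for (i in seq_len(n)) S[i + 1L, i] <- S[i + 1L, i] + step[i]
  f <- apply(S, 1L, fn)
  neval <- n + 1L
  scale0 <- max(abs(x0), 1)
  while (neval < maxeval) {
    ord <- order(f)
    S <- S[ord, , drop = FALSE]; f <- f[ord]
    spread <- f[n + 1L] - f[1L]
    size <- max(abs(sweep(S[-1L, , drop = FALSE], 2L, S[1L, ])))
    if (f[1L] <= abstol ||
        (spread <= reltol * (abs(f[1L]) + reltol) && size <= stol * scale0))
      return(list(par = S[1L, ], value = f[1L], converged = TRUE, neval = neval))
    cen <- colMeans(S[-(n + 1L), , drop = FALSE])
    xr <- cen + (cen - S[n + 1L, ])
    fr <- fn(xr); neval <- neval + 1L
    if (fr < f[1L]) {
      xe <- cen + 2 * (cen - S[n + 1L, ])
      fe <- fn(xe); neval <- neval + 1L
      if (fe < fr) { S[n + 1L, ] <- xe; f[n + 1L] <- fe }
      else { S[n + 1L, ] <- xr; f[n + 1L] <- fr }
    } else if (fr < f[n]) {
      S[n + 1L, ] <- xr; f[n + 1L] <- fr
    } else {
      if (fr < f[n + 1L]) {
        xc <- cen + 0.5 * (xr - cen)          # outside contraction
      } else {
        xc <- cen - 0.5 * (cen - S[n + 1L, ]) # inside contraction
      }
      fc <- fn(xc); neval <- neval + 1L
      if (fc < min(fr, f[n + 1L])) {
        S[n + 1L, ] <- xc; f[n + 1L] <- fc
      } else {                                 # shrink toward the best vertex
        for (i in 2:(n + 1L)) {
          S[i, ] <- S[1L, ] + 0.5 * (S[i, ] - S[1L, ])
          f[i] <- fn(S[i, ])
        }
        neval <- neval + n
      }
    }
  }
  ord <- order(f)
  list(par = S[ord[1L], ], value = f[ord[1L]], converged = FALSE, neval = neval)
}
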