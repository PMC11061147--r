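# Shared fixture builders; everything is generated in code.

# evenly distributed unit directions (Fibonacci sphere lattice)
fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# exact points on an ellipsoid surface
ellipsoidPoints <- function(n, center = c(0, 0, 0), semiAxes = c(12.5, 12, 11.5),
                            orientation = diag(3)) {
  e <- ellipsoidFromGeometry(center, semiAxes, orientation)
  u <- fibSphere(n)
  sweep(u * drop(ellipsoidRadius(e, u)), 2, center, "+")
}

# random rotation matrix (det +1), seeded by the caller
randomRotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# standardized posterior cloud from a phantom spec
phantomPosterior <- function(spec, minPoints = 300L) {
  ph <- makeSurface(spec)
  cloud <- standardizeFrame(ph$points, ph$landmarks, ph$laterality)
  selectPosterior(cloud, minPoints = minPoints)
}

# brute-force distance oracle, independent of the Lagrange/Newton solver:
# dense sampling of the parametric surface chart, then a 2D simplex polish
# of the best (theta, phi) candidate to remove the tangential grid gap
bruteForceDistance <- function(model, p, nTheta = 1600L, nPhi = 625L) {
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-1L]
  ph <- seq(0, pi, length.out = nPhi)
  s <- semiAxes(model)
  best <- Inf
  bestPar <- c(0, 0)
  # principal-frame point
  y <- drop(orientation(model) %*% (p - ellipsoidCenter(model)))
  for (chunk in split(ph, ceiling(seq_along(ph) / 64))) {
    grid <- expand.grid(th = th, ph = chunk)
    X <- cbind(s[1] * sin(grid$ph) * cos(grid$th),
               s[2] * sin(grid$ph) * sin(grid$th),
               s[3] * cos(grid$ph))
    d2 <- (X[, 1] - y[1])^2 + (X[, 2] - y[2])^2 + (X[, 3] - y[3])^2
    i <- which.min(d2)
    if (d2[i] < best) {
      best <- d2[i]
      bestPar <- c(grid$th[i], grid$ph[i])
    }
  }
  f <- function(par) {
    x <- c(s[1] * sin(par[2]) * cos(par[1]),
           s[2] * sin(par[2]) * sin(par[1]),
           s[3] * cos(par[2]))
    sum((x - y)^2)
  }
  opt <- stats::optim(bestPar, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 500))
  sqrt(min(best, opt$value))
}
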