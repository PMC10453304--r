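# Independent adaptive integrator (Dormand-Prince 5(4) with step control),
# used as a high-accuracy oracle against the package's fixed-step RK4 path.
# Deliberately shares no code with the implementation under test.
ode_oracle <- function(deriv, y0, times, rtol = 1e-10, atol = 1e-12) {
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  step <- function(y, h) {
    k <- matrix(0, 7, length(y))
    k[1, ] <- deriv(y)
    for (s in 2:7) {
      acc <- y
      for (j in seq_len(s - 1)) acc <- acc + h * a[[s - 1]][j] * k[j, ]
      k[s, ] <- deriv(acc)
    }
    y5 <- y + h * colSums(b5 * k)
    y4 <- y + h * colSums(b4 * k)
    list(y = y5, err = max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5)))))
  }
  out <- matrix(NA_real_, length(times), length(y0))
  t <- 0; y <- as.numeric(y0); h <- 1e-3
  for (i in seq_along(times)) {
    target <- times[i]
    while (t < target - 1e-14) {
      h_try <- min(h, target - t)
      res <- step(y, h_try)
      if (res$err <= 1) {
        t <- t + h_try
        y <- res$y
        h <- h_try * min(5, max(0.2, 0.9 * res$err^(-0.2)))
      } else {
        h <- h_try * max(0.2, 0.9 * res$err^(-0.2))
      }
    }
    out[i, ] <- y
  }
  out
}

l96_rhs <- function(params) {
  n <- params$n_dims
  F <- params$forcing
  function(x) {
    (x[c(2:n, 1)] - x[c(n - 1, n, 1:(n - 2))]) * x[c(n, 1:(n - 1))] - x + F
  }
}
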