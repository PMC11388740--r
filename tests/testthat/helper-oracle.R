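# Independent brute-force transcription of the iterative centre-of-mass
# refinement: explicit loops, no vectorisation, no shared code with the
# package implementation.  Window is the d x d neighbourhood (half-width
# (d - 1) / 2) centred on the rounded current estimate; out-of-bounds
# pixels contribute zero mass.
refine_oracle <- function(h, x0, y0, d = 5, N = 3) {
  x <- x0
  y <- y0
  half <- (d - 1) %/% 2
  H <- nrow(h)
  W <- ncol(h)
  n <- 0
  while (n < N) {
    xn <- floor(x + 0.5)
    yn <- floor(y + 0.5)
    S <- 0
    sx <- 0
    sy <- 0
    for (i in -half:half) {
      for (j in -half:half) {
        xi <- xn + i
        yj <- yn + j
        v <- 0
        if (xi >= 0 && xi <= W - 1 && yj >= 0 && yj <= H - 1)
          v <- h[yj + 1, xi + 1]
        S <- S + v
        sx <- sx + v * xi
        sy <- sy + v * yj
      }
    }
    if (S == 0) return(c(x0, y0))
    x <- sx / S
    y <- sy / S
    n <- n + 1
  }
  c(x, y)
}
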