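# Independent oracles used across tests.

# Exhaustive Mann-Whitney: enumerate every assignment of the pooled values
# to group A, compute U for each, and read the two-sided p-value off the
# permutation distribution.
enumerate_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  u_obs <- u_stat(x, y)
  mu <- n1 * length(y) / 2
  # two-sided: as or more extreme in distance from the mean
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = min(1, p))
}

# Direct least-squares Savitzky-Golay: fit a polynomial to each window and
# evaluate at the center (edges: evaluate the terminal-window fit).
savgol_direct <- function(y, window, polyorder) {
  n <- length(y)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, min(i - half, n - window + 1))
    idx <- lo:(lo + window - 1)
    fit <- lm(y[idx] ~ poly(idx, polyorder, raw = TRUE))
    out[i] <- unname(predict(fit, data.frame(idx = i)))
  }
  out
}

# Brute-force point-in-polygon at pixel centers: mgcv's crossing test plus
# an explicit on-boundary check (boundary pixels count as inside).
pip_oracle <- function(poly, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py))
  on_boundary <- rep(FALSE, length(px))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    seg2 <- (bx - ax)^2 + (by - ay)^2
    if (seg2 == 0) next
    t <- pmin(1, pmax(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / seg2))
    d2 <- (px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2
    on_boundary <- on_boundary | d2 < 1e-18
  }
  matrix(inside | on_boundary, h, w)
}

# small wavelength grid used by fast tests
wl_small <- function(n = 17) seq(400, 720, length.out = n)
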