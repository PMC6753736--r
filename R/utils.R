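# Internal numeric helpers. All lengths are in cm, public angles in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap an angular difference into (-180, 180]
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

skew3 <- function(v) {
  matrix(c(0, -v[3L], v[2L],
           v[3L], 0, -v[1L],
           -v[2L], v[1L], 0), 3L, 3L, byrow = TRUE)
}

# Rodrigues rotation matrix for rotation vector w (radians)
rodrigues <- function(w) {
  th <- vnorm(w)
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

# golden angle (deg), used by the deterministic phantom layouts
GOLDEN_ANGLE <- 137.50776405003785
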