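# Internal numerical and validation helpers.

# Gauss-Legendre half-nodes/weights used by the bivariate-normal CDF.
.gl6 <- list(
  x = c(0.9324695142031521, 0.6612093864662645, 0.2386191860831969),
  w = c(0.1713244923791704, 0.3607615730481386, 0.4679139345726910)
)
.gl12 <- list(
  x = c(0.9815606342467192, 0.9041172563704749, 0.7699026741943047,
        0.5873179542866175, 0.3678314989981802, 0.1252334085114689),
  w = c(0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
        0.2031674267230659, 0.2334925365383548, 0.2491470458134028)
)
.gl20 <- list(
  x = c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
        0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
        0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
        0.07652652113349733),
  w = c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
        0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
        0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
        0.1527533871307259)
)

# Upper-orthant bivariate normal probability P(X > h, Y > k) for scalar
# correlation r and vectors h, k; Genz (2004) quadrature, accurate to ~1e-15.
.bvnd_upper <- function(h, k, r) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  if (abs(r) < 0.3) gl <- .gl6 else if (abs(r) < 0.75) gl <- .gl12 else gl <- .gl20

  if (abs(r) < 0.925) {
    hk <- h * k
    bvn <- numeric(n)
    if (r != 0) {
      hs <- (h * h + k * k) / 2
      asr <- asin(r)
      for (i in seq_along(gl$x)) {
        for (is in c(-1, 1)) {
          sn <- sin(asr * (is * gl$x[i] + 1) / 2)
          bvn <- bvn + gl$w[i] * exp((sn * hk - hs) / (1 - sn * sn))
        }
      }
      bvn <- bvn * asr / (4 * pi)
    }
    return(bvn + pnorm(-h) * pnorm(-k))
  }

  # high-|r| branch (Genz's tail transformation)
  twopi <- 2 * pi
  if (r < 0) k <- -k
  hk <- h * k
  bvn <- numeric(n)
  if (abs(r) < 1) {
    as_ <- (1 - r) * (1 + r)
    a <- sqrt(as_)
    bs <- (h - k)^2
    cc <- (4 - hk) / 8
    d <- (12 - hk) / 16
    asr <- -(bs / as_ + hk) / 2
    ok <- asr > -100
    bvn[ok] <- (a * exp(asr) * (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 +
                                  cc * d * as_ * as_ / 5))[ok]
    ok2 <- -hk < 100
    if (any(ok2)) {
      b <- sqrt(bs)
      corr <- (exp(-hk / 2) * sqrt(twopi) * pnorm(-b / a) * b *
                 (1 - cc * bs * (1 - d * bs / 5) / 3))
      bvn[ok2] <- bvn[ok2] - corr[ok2]
    }
    a2 <- a / 2
    for (i in seq_along(gl$x)) {
      for (is in c(-1, 1)) {
        xs <- (a2 * (is * gl$x[i] + 1))^2
        rs <- sqrt(1 - xs)
        asr <- -(bs / xs + hk) / 2
        ok <- asr > -100
        if (any(ok)) {
          term <- a2 * gl$w[i] * exp(asr) *
            (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
               (1 + cc * xs * (1 + d * xs)))
          bvn[ok] <- bvn[ok] + term[ok]
        }
      }
    }
    bvn <- -bvn / twopi
  }
  if (r > 0) {
    bvn <- bvn + pnorm(-pmax(h, k))
  } else {
    bvn <- -bvn
    hi <- k > h
    bvn[hi] <- bvn[hi] + (pnorm(k) - pnorm(h))[hi]
  }
  bvn
}

#' Bivariate standard-normal CDF
#'
#' `P(X <= h, Y <= k)` for standard bivariate normal `(X, Y)` with
#' correlation `rho`. Vectorized over `h` and `k`; `rho` must be a scalar in
#' `[-1, 1]`. Used internally for polychoric rectangle probabilities.
#'
#' @param h,k Numeric vectors of upper integration limits (recycled).
#' @param rho Scalar latent correlation.
#' @return Numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0)    # 0.25
#' pbvnorm(0, 0, 0.5)  # 1/4 + asin(0.5)/(2*pi)
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), rho >= -1, rho <= 1)
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n); k <- rep_len(as.numeric(k), n)
  out <- numeric(n)
  lo <- h == -Inf | k == -Inf
  hi_h <- h == Inf; hi_k <- k == Inf
  plain <- !(lo | hi_h | hi_k)
  out[hi_h & !lo] <- pnorm(k[hi_h & !lo])
  out[hi_k & !lo & !hi_h] <- pnorm(h[hi_k & !lo & !hi_h])
  if (any(plain)) {
    if (rho == 1) {
      out[plain] <- pnorm(pmin(h[plain], k[plain]))
    } else if (rho == -1) {
      out[plain] <- pmax(0, pnorm(h[plain]) + pnorm(k[plain]) - 1)
    } else {
      out[plain] <- .bvnd_upper(-h[plain], -k[plain], rho)
    }
  }
  pmin(pmax(out, 0), 1)
}

# error helpers ---------------------------------------------------------------

.stop_config <- function(msg, class = "trionurture_config_error") {
  abort(msg, class = c(class, "trionurture_error"))
}

.check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    .stop_config(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(lo), format(hi)))
  }
  invisible(x)
}

# Derive a stage seed from a master seed and a label, stably across sessions.
# Kept below 2^31 so it is always a valid R integer.
.derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 48271 + h * 1299721) %% 2147483647)
}
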