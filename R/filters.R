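# Butterworth design in zero-pole-gain form with second-order-section
# (biquad cascade) application.
#
# The conditioning chain needs very narrow normalized bands (0.1 Hz lowpass
# and a 0.2-0.5 Hz stop band at a 100 Hz rate). Expanded transfer-function
# polynomials of such filters are numerically degenerate -- rounding pushes
# poles outside the unit circle and the filter diverges -- so the design is
# kept in zpk form (analog Butterworth prototype, band transform, bilinear
# transform) and applied as a cascade of second-order sections, each of
# which is well conditioned.

butter_zpk <- function(order, w, type = c("low", "pass", "stop")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1))
    stop("normalized frequencies must lie in (0, 1)")
  fs <- 2
  warped <- 2 * fs * tan(pi * w / fs)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k - 1 + order) / (2 * order))  # unit analog prototype
  z <- complex(0)
  g <- 1
  if (type == "low") {
    w0 <- warped
    p <- w0 * p
    g <- w0^order
  } else if (type == "pass") {
    bw <- warped[2L] - warped[1L]
    w0 <- sqrt(warped[1L] * warped[2L])
    plp <- p * bw / 2
    p <- c(plp + sqrt(plp^2 - w0^2), plp - sqrt(plp^2 - w0^2))
    z <- rep(0 + 0i, order)
    g <- bw^order
  } else {  # stop
    bw <- warped[2L] - warped[1L]
    w0 <- sqrt(warped[1L] * warped[2L])
    g <- 1 / Re(prod(-p))  # = 1 for Butterworth (no prototype zeros)
    foo <- (bw / 2) / p
    p <- c(foo + sqrt(foo^2 - w0^2), foo - sqrt(foo^2 - w0^2))
    z <- rep_len(c(1i * w0, -1i * w0), 2L * order)
  }
  # bilinear transform (fs = 2 convention)
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gd <- g * Re(prod(fs2 - z) / prod(fs2 - p))
  degree <- length(p) - length(z)
  zd <- c(zd, rep(-1 + 0i, degree))
  list(z = zd, p = pd, g = gd)
}

# Group complex values into conjugate pairs (assumes even count, all values
# either in conjugate pairs or real in pairs).
conj_pairs <- function(v) {
  used <- logical(length(v))
  pairs <- list()
  for (i in seq_along(v)) {
    if (used[i]) next
    used[i] <- TRUE
    cand <- which(!used)
    j <- cand[which.min(abs(v[cand] - Conj(v[i])))]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(v[i], v[j])
  }
  pairs
}

# Convert zpk to an SOS matrix (rows: b0 b1 b2 1 a1 a2). Pole pairs closest
# to the unit circle go last; the overall gain multiplies the first section.
zpk2sos <- function(zpk) {
  pp <- conj_pairs(zpk$p)
  zp <- conj_pairs(zpk$z)
  if (length(pp) != length(zp))
    stop("internal: unbalanced pole/zero pairs")
  ord <- order(vapply(pp, function(q) abs(1 - abs(q[1L])), numeric(1)),
               decreasing = TRUE)
  pp <- pp[ord]
  # pair each pole pair with the nearest remaining zero pair
  sos <- matrix(0, nrow = length(pp), ncol = 6L)
  left <- seq_along(zp)
  for (i in seq_along(pp)) {
    d <- vapply(left, function(j) abs(zp[[j]][1L] - pp[[i]][1L]), numeric(1))
    j <- left[which.min(d)]
    left <- setdiff(left, j)
    b <- Re(c(1, -(zp[[j]][1L] + zp[[j]][2L]), zp[[j]][1L] * zp[[j]][2L]))
    a <- Re(c(1, -(pp[[i]][1L] + pp[[i]][2L]), pp[[i]][1L] * pp[[i]][2L]))
    sos[i, ] <- c(b, a)
  }
  sos[1L, 1:3] <- sos[1L, 1:3] * zpk$g
  sos
}

design_butter_sos <- function(order, w, type) zpk2sos(butter_zpk(order, w, type))

# One forward pass of a biquad cascade with step-state initial conditions
# (each section is initialised to its steady response to a step of the
# section input's first value, so constant signals pass without transients).
sos_forward <- function(x, sos) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]
    a <- sos[i, 4:6]
    x0 <- x[1L]
    dc <- sum(b) / sum(a)
    x <- as.numeric(signal::filter(b, a, x, init.x = rep(x0, 2L),
                                   init.y = rep(x0 * dc, 2L)))
  }
  x
}

# Zero-phase (forward-backward) application of an SOS cascade with
# odd-reflection padding; the input mean is removed and restored so signals
# in a DC passband keep their mean exactly.
sos_filtfilt <- function(x, sos, padlen) {
  n <- length(x)
  padlen <- max(3L, min(as.integer(padlen), n - 2L))
  mu <- mean(x)
  x <- x - mu
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- sos_forward(ext, sos)
  y <- rev(sos_forward(rev(y), sos))
  y[(padlen + 1L):(padlen + n)] + mu
}
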