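# Independent oracles, deliberately implemented with different algorithms
# than the package (explicit per-pixel counting, label propagation, closed
# forms) so they can cross-check it.

# majority filter by explicit neighborhood counting, pixel by pixel
oracleMajority <- function(m, radius, passes) {
  h <- nrow(m); w <- ncol(m)
  offs <- list()
  for (dy in -radius:radius) for (dx in -radius:radius)
    if (dy * dy + dx * dx <= radius * radius)
      offs[[length(offs) + 1L]] <- c(dy, dx)
  cur <- m
  for (p in seq_len(passes)) {
    nxt <- cur
    for (i in seq_len(h)) for (j in seq_len(w)) {
      tt <- 0L; vv <- 0L
      for (o in offs) {
        ii <- i + o[1L]; jj <- j + o[2L]
        if (ii >= 1L && ii <= h && jj >= 1L && jj <= w) {
          vv <- vv + 1L
          if (cur[ii, jj]) tt <- tt + 1L
        }
      }
      nxt[i, j] <- (2L * tt >= vv)
    }
    cur <- nxt
  }
  cur
}

# 4-connected component labels by iterative minimum-label propagation
oracleComponents <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(as.numeric(seq_len(h * w)), h, w)
  lab[!m] <- NA
  repeat {
    up <- rbind(NA, lab[-h, , drop = FALSE])
    dn <- rbind(lab[-1L, , drop = FALSE], NA)
    lf <- cbind(NA, lab[, -w, drop = FALSE])
    rt <- cbind(lab[, -1L, drop = FALSE], NA)
    new <- pmin(lab, up, dn, lf, rt, na.rm = TRUE)
    new[!m] <- NA
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# OLS by hand-solved normal equations
oracleOLS <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  syy <- sum(y * y)
  r2 <- (n * sxy - sx * sy)^2 / ((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, r2 = r2)
}

# boundary pixels = region minus its 4-neighborhood erosion
oracleBoundarySet <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(FALSE, m[-h, , drop = FALSE])
  dn <- rbind(m[-1L, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -w, drop = FALSE])
  rt <- cbind(m[, -1L, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

discMask <- function(h, w, cr, cc, R) {
  DY <- matrix(seq_len(h) - cr, h, w)
  DX <- matrix(seq_len(w) - cc, h, w, byrow = TRUE)
  DY^2 + DX^2 <= R^2
}

pixelKey <- function(px) sort(paste(px[, 1L], px[, 2L]))
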