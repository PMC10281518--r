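# Independent brute-force oracles. These deliberately use naive,
# loop-based code paths so that agreement with the package is a real
# cross-check, not a tautology.

# rows-first alternating median sweeps, run to (numerical) convergence;
# occasional long plateaus on even-dimension grids need a generous cap
oracleMedianPolish <- function(x, maxIter = 5000L, tol = 1e-13) {
  med <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) return(0)
    v <- sort(v)
    if (n %% 2L == 1L) v[(n + 1L) %/% 2L] else (v[n %/% 2L] + v[n %/% 2L + 1L]) / 2
  }
  z <- x
  nr <- nrow(x)
  nc <- ncol(x)
  rowEff <- numeric(nr)
  colEff <- numeric(nc)
  overall <- 0
  scale0 <- stats::median(abs(x - stats::median(x, na.rm = TRUE)),
                          na.rm = TRUE)
  if (!is.finite(scale0) || scale0 == 0) scale0 <- 1
  for (it in seq_len(maxIter)) {
    change <- 0
    for (i in seq_len(nr)) {
      m <- med(z[i, ])
      z[i, ] <- z[i, ] - m
      rowEff[i] <- rowEff[i] + m
      change <- change + abs(m)
    }
    d <- stats::median(colEff)
    colEff <- colEff - d
    overall <- overall + d
    for (j in seq_len(nc)) {
      m <- med(z[, j])
      z[, j] <- z[, j] - m
      colEff[j] <- colEff[j] + m
      change <- change + abs(m)
    }
    d <- stats::median(rowEff)
    rowEff <- rowEff - d
    overall <- overall + d
    if (change < tol * scale0) break
  }
  list(overall = overall, rowEffects = rowEff, colEffects = colEff,
       residuals = z, nIter = it)
}

# Crofton 4-direction perimeter by explicit per-window pattern matching
# over the padded mask (window pattern string -> weight)
oracleCroftonPerimeter <- function(mask) {
  s2 <- sqrt(2)
  w <- c(
    "0000" = 0,
    "0001" = pi / 4 * (1 + 1 / s2),
    "0010" = pi / (4 * s2),
    "0011" = pi / (2 * s2),
    "0100" = 0,
    "0101" = pi / 4 * (1 + 1 / s2),
    "0110" = 0,
    "0111" = pi / (4 * s2),
    "1000" = pi / 4,
    "1001" = pi / 2,
    "1010" = pi / (4 * s2),
    "1011" = pi / (4 * s2),
    "1100" = pi / 4,
    "1101" = pi / 2,
    "1110" = 0,
    "1111" = 0
  )
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0L
  total <- 0
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in seq_len(ncol(m) - 1L)) {
      pat <- paste0(m[i, j], m[i, j + 1L], m[i + 1L, j], m[i + 1L, j + 1L])
      total <- total + w[[pat]]
    }
  }
  total
}

# robust z from first principles: sort-based median and MAD
oracleRobustZ <- function(x, library) {
  med <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
  }
  center <- med(library)
  scale <- 1.4826 * med(abs(library - center))
  (x - center) / scale
}

# pooled-variance two-sample t from the textbook formula
oracleTTest <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# one-way ANOVA F from explicit sums of squares
oracleAnovaF <- function(groups) {
  all_ <- unlist(groups)
  gm <- mean(all_)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all_) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# exhaustive background-box oracle: distribution of the estimator over
# every admissible box (ignoring the disjointness constraint, which only
# narrows the distribution)
oracleBackgroundDistribution <- function(image, mask, boxSize = 8L) {
  maxima <- c()
  for (r in seq_len(nrow(mask) - boxSize + 1L)) {
    for (c_ in seq_len(ncol(mask) - boxSize + 1L)) {
      sub <- mask[r:(r + boxSize - 1L), c_:(c_ + boxSize - 1L)]
      if (all(sub))
        maxima <- c(maxima, max(image[r:(r + boxSize - 1L),
                                      c_:(c_ + boxSize - 1L)]))
    }
  }
  maxima
}
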