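# Independent brute-force oracles: deliberately naive (explicit loops and
# enumerations), sharing no code with the package implementations.

# Enumerate every grid cell of a map (r <= outer), returning value, polar
# coordinates and the cell's area weight (proportional to radius).
oracle_cells <- function(map, outer = 2.5) {
  g <- map$grid
  out <- list()
  for (i in seq_along(g$radii)) {
    if (g$radii[i] > outer + 1e-12) next
    for (j in seq_along(g$angles)) {
      out[[length(out) + 1L]] <- data.frame(
        r = g$radii[i], a = g$angles[j], v = map$values[i, j], w = g$radii[i])
    }
  }
  do.call(rbind, out)
}

oracle_octant <- function(a) {
  centers <- c(T = 0, ST = 45, S = 90, SN = 135, N = 180, IN = 225, I = 270,
               IT = 315)
  for (nm in names(centers)) {
    d <- abs(((a - centers[[nm]] + 180) %% 360) - 180)
    lo <- abs(((a - centers[[nm]] + 22.5 + 180) %% 360) - 180)
    if (d < 22.5 - 1e-9) return(nm)
    if (abs(d - 22.5) < 1e-9 && ((a - centers[[nm]]) %% 360) > 180) return(nm)
  }
  # boundary at center + 22.5 belongs to the next octant counterclockwise
  for (nm in names(centers)) {
    if (abs(((a - (centers[[nm]] - 22.5)) %% 360)) < 1e-9) return(nm)
  }
  stop("unclassified angle ", a)
}

oracle_zone_mean <- function(map, zone, outer = 2.5, central = 1.0) {
  cells <- oracle_cells(map, outer)
  y <- cells$r * sin(cells$a * pi / 180)
  sel <- switch(zone,
    central = cells$r <= central + 1e-12,
    annulus = cells$r > central + 1e-12,
    superior = cells$r > central + 1e-12 & y > 1e-12,
    inferior = cells$r > central + 1e-12 & y < -1e-12,
    cells$r > central + 1e-12 &
      vapply(cells$a, oracle_octant, character(1)) == zone)
  sum(cells$v[sel] * cells$w[sel]) / sum(cells$w[sel])
}

# Exhaustive scan for the extremes (vertex included, zero weight), with the
# smallest-radius-then-smallest-angle tie-break.
oracle_extremes <- function(map, outer = 2.5) {
  cells <- oracle_cells(map, outer)
  cells <- rbind(data.frame(r = 0, a = 0, v = map$center_value, w = 0), cells)
  cells <- cells[order(cells$r, cells$a), ]
  best_min <- best_max <- cells[1, ]
  for (i in seq_len(nrow(cells))) {
    if (cells$v[i] < best_min$v) best_min <- cells[i, ]
    if (cells$v[i] > best_max$v) best_max <- cells[i, ]
  }
  list(min = best_min, max = best_max)
}

oracle_weighted_median <- function(v, w) {
  o <- order(v); v <- v[o]; w <- w[o]
  acc <- 0; half <- sum(w) / 2
  for (i in seq_along(v)) {
    acc <- acc + w[i]
    if (acc >= half) return(v[i])
  }
  v[length(v)]
}

# Two-pass weighted population variance.
oracle_weighted_sd <- function(v, w) {
  m <- sum(v * w) / sum(w)
  acc <- 0
  for (i in seq_along(v)) acc <- acc + w[i] * (v[i] - m)^2
  sqrt(acc / sum(w))
}

# Pair-counting AUC: fraction of (pos, neg) pairs with pos > neg, ties 0.5.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

# Kruskal-Wallis H from first principles: midranks by pairwise counting,
# rank-sum statistic, explicit tie correction.
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  rk <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(values < values[i])
    eq <- sum(values == values[i])
    rk[i] <- less + (eq + 1) / 2
  }
  h <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    h <- h + sum(rk[sel])^2 / sum(sel)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# One-sample KS statistic against N(mean, sd) by full ECDF enumeration.
oracle_ks_stat <- function(x) {
  x <- sort(x); n <- length(x)
  f <- pnorm(x, mean(x), sd(x))
  d <- 0
  for (i in seq_len(n))
    d <- max(d, abs(i / n - f[i]), abs((i - 1) / n - f[i]))
  d
}

# Binormal AUC by numerical integration of P(X_pos > X_neg).
oracle_binormal_quad <- function(mu_p, sd_p, mu_n, sd_n) {
  f <- function(x) dnorm(x, mu_p, sd_p) * pnorm(x, mu_n, sd_n)
  lo <- min(mu_p - 12 * sd_p, mu_n - 12 * sd_n)
  hi <- max(mu_p + 12 * sd_p, mu_n + 12 * sd_n)
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
}
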