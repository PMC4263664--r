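# Independent oracles and fixture builders used across the suite.
# Every oracle is deliberately naive (enumeration, double loops, closed
# forms) and shares no code path with the package implementation.

# ---- fixtures ---------------------------------------------------------------

fixture_disk_image <- function(size = 64, center = c(32, 30), radius = 15,
                               inside = 100, outside = 20, noise_sd = 0,
                               bias_slope = 0, seed = NULL) {
  xs <- matrix(0:(size - 1), size, size, byrow = TRUE)
  ys <- matrix(0:(size - 1), size, size)
  disk <- (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
  img <- matrix(outside, size, size)
  img[disk] <- inside
  if (bias_slope != 0) img <- img * (1 + bias_slope * (xs / size - 0.5))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
  }
  list(image = img, disk = disk, xs = xs, ys = ys)
}

circle_points <- function(center, radius, n = 100) {
  th <- 2 * pi * (0:(n - 1)) / n
  data.frame(x = center[1] + radius * cos(th), y = center[2] - radius * sin(th))
}

# ---- dynamic-programming oracles -------------------------------------------

# Exhaustive enumeration of every delta-feasible closed path. Returns the
# minimal augmented cost and the path selected by the stated tie-break:
# smallest start row, then smallest end row, then lexicographically smallest
# rows read backwards from column N-1.
dp_oracle_enum <- function(feature, mask, delta, w, gamma) {
  m <- nrow(feature); n <- ncol(feature)
  step <- w * (1 - feature); step[!mask] <- Inf
  moves <- as.matrix(expand.grid(rep(list((-delta):delta), n - 1)))
  best_cost <- Inf; best_path <- NULL
  for (s in seq_len(m)) {
    if (!is.finite(step[s, 1])) next
    paths <- matrix(s, nrow(moves), n)
    for (j in 2:n) paths[, j] <- paths[, j - 1] + moves[, j - 1]
    ok <- rep(TRUE, nrow(paths))
    for (j in 2:n) ok <- ok & paths[, j] >= 1 & paths[, j] <= m
    ok <- ok & abs(paths[, n] - s) <= delta
    if (!any(ok)) next
    p <- paths[ok, , drop = FALSE]
    cost <- step[p[, 1]]
    for (j in 2:n) cost <- cost + step[p[, j] + (j - 1) * m]
    cost <- cost + gamma * abs(p[, n] - p[, 1])
    fin <- is.finite(cost)
    if (!any(fin)) next
    p <- p[fin, , drop = FALSE]; cost <- cost[fin]
    cmin <- min(cost)
    if (cmin < best_cost - 1e-12) {
      cand <- p[cost <= cmin + 1e-12, , drop = FALSE]
      key <- cand[, c(1, n, (n - 1):2), drop = FALSE]
      ord <- do.call(order, lapply(seq_len(ncol(key)), function(k) key[, k]))
      best_cost <- cmin
      best_path <- cand[ord[1], ]
    }
  }
  list(cost = best_cost, path = best_path)
}

# Independent shortest-path oracle (igraph Dijkstra on the column DAG),
# exact for the minimal cost; used where full enumeration is too large.
dp_oracle_igraph <- function(feature, mask, delta, w, gamma) {
  m <- nrow(feature); n <- ncol(feature)
  step <- w * (1 - feature); step[!mask] <- Inf
  node <- function(i, j) (j - 1) * m + i
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (j in 1:(n - 1)) {
    for (i in seq_len(m)) {
      if (!is.finite(step[i, j])) next
      for (k in max(1, i - delta):min(m, i + delta)) {
        if (!is.finite(step[k, j + 1])) next
        from <- c(from, node(i, j)); to <- c(to, node(k, j + 1))
        wt <- c(wt, step[k, j + 1])
      }
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = m * n, directed = TRUE)
  best <- Inf
  for (s in seq_len(m)) {
    if (!is.finite(step[s, 1])) next
    ends <- seq(max(1, s - delta), min(m, s + delta))
    d <- suppressWarnings(igraph::distances(g, v = node(s, 1),
                                            to = node(ends, n),
                                            mode = "out", weights = wt))
    tot <- step[s, 1] + as.numeric(d) + gamma * abs(ends - s)
    best <- min(best, tot, na.rm = TRUE)
  }
  best
}

random_dp_instance <- function(m, n, delta, gamma) {
  feature <- matrix(stats::runif(m * n), m, n)
  mask <- matrix(stats::runif(m * n) > 0.15, m, n)
  for (j in which(colSums(mask) == 0)) mask[sample.int(m, 1), j] <- TRUE
  list(feature = feature, mask = mask,
       params = lvseg::dp_params(delta = delta, w = 1, gamma = gamma))
}

# ---- geometry oracles -------------------------------------------------------

# Brute-force convex hull membership: a point is a hull vertex iff some line
# through it leaves all other points strictly on one side.
hull_oracle_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
      if (all(cr >= -1e-9) || all(cr <= 1e-9)) { on_hull[i] <- TRUE; break }
    }
  }
  pts[on_hull, , drop = FALSE]
}

# Quadratic-time point-to-segment APD oracle.
apd_oracle <- function(auto, manual, spacing = 1) {
  seg_dist <- function(px, py, x1, y1, x2, y2) {
    ex <- x2 - x1; ey <- y2 - y1
    L2 <- ex^2 + ey^2
    if (L2 < 1e-12) return(sqrt((px - x1)^2 + (py - y1)^2))
    t <- max(0, min(1, ((px - x1) * ex + (py - y1) * ey) / L2))
    sqrt((px - (x1 + t * ex))^2 + (py - (y1 + t * ey))^2)
  }
  nm <- nrow(manual)
  total <- 0
  for (i in seq_len(nrow(auto))) {
    dmin <- Inf
    for (k in seq_len(nm)) {
      k2 <- if (k == nm) 1L else k + 1L
      dmin <- min(dmin, seg_dist(auto$x[i], auto$y[i],
                                 manual$x[k], manual$y[k],
                                 manual$x[k2], manual$y[k2]))
    }
    total <- total + dmin
  }
  total / nrow(auto) * spacing
}

# ---- LBF oracles ------------------------------------------------------------

# Truncated replicate-padded Gaussian kernel, identical contract to the
# implementation's stated design (half-width floor(2 sigma) + 1, normalised).
oracle_kernel <- function(sigma) {
  h <- floor(2 * sigma) + 1
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- outer(g, g)
  list(k = k / sum(k), h = h)
}

oracle_conv_at <- function(img, kern, i, j) {
  h <- kern$h; k <- kern$k
  nr <- nrow(img); nc <- ncol(img)
  acc <- 0
  for (di in -h:h) for (dj in -h:h) {
    ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
    acc <- acc + k[di + h + 1, dj + h + 1] * img[ii, jj]
  }
  acc
}

oracle_conv <- function(img, kern) {
  out <- img * 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    out[i, j] <- oracle_conv_at(img, kern, i, j)
  out
}

# Direct double-loop computation of the locally fitted intensities.
oracle_local_fits <- function(image, phi, sigma, eps) {
  kern <- oracle_kernel(sigma)
  H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  f1 <- oracle_conv(H * image, kern) / pmax(oracle_conv(H, kern), 1e-10)
  f2 <- oracle_conv((1 - H) * image, kern) / pmax(oracle_conv(1 - H, kern), 1e-10)
  list(f1 = f1, f2 = f2)
}

# Full naive single evolution step (loops everywhere, replicate boundaries).
oracle_lbf_step <- function(image, phi, p) {
  nr <- nrow(phi); nc <- ncol(phi)
  kern <- oracle_kernel(p$sigma)
  fits <- oracle_local_fits(image, phi, p$sigma, p$epsilon)
  kone <- oracle_conv(matrix(1, nr, nc), kern)
  e1 <- image^2 * kone - 2 * image * oracle_conv(fits$f1, kern) +
    oracle_conv(fits$f1^2, kern)
  e2 <- image^2 * kone - 2 * image * oracle_conv(fits$f2, kern) +
    oracle_conv(fits$f2^2, kern)
  at <- function(m, i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  gx <- phi * 0; gy <- phi * 0
  for (i in 1:nr) for (j in 1:nc) {
    gx[i, j] <- (at(phi, i, j + 1) - at(phi, i, j - 1)) / 2
    gy[i, j] <- (at(phi, i + 1, j) - at(phi, i - 1, j)) / 2
  }
  nrm <- sqrt(gx^2 + gy^2) + 1e-10
  nx <- gx / nrm; ny <- gy / nrm
  curv <- phi * 0; lap <- phi * 0
  for (i in 1:nr) for (j in 1:nc) {
    curv[i, j] <- (at(nx, i, j + 1) - at(nx, i, j - 1)) / 2 +
      (at(ny, i + 1, j) - at(ny, i - 1, j)) / 2
    lap[i, j] <- at(phi, i + 1, j) + at(phi, i - 1, j) +
      at(phi, i, j + 1) + at(phi, i, j - 1) - 4 * phi[i, j]
  }
  dirac <- (p$epsilon / pi) / (p$epsilon^2 + phi^2)
  nu <- if (is.null(p$nu)) 0.003 * diff(range(image))^2 else p$nu
  force <- -dirac * (p$lambda1 * e1 - p$lambda2 * e2) + nu * dirac * curv +
    p$mu * (lap - curv)
  phi + p$timestep * force
}

# ---- misc -------------------------------------------------------------------

# Closed-form ordinary least squares (normal equations written out).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
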