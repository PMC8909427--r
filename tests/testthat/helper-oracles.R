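# Independent brute-force oracles. Everything here is written as the
# plainest possible enumeration, deliberately sharing no code with the
# package internals it checks.

# random small mask with at least one foreground voxel
random_mask <- function(dim3, p = 0.4, spacing = c(1, 1, 1)) {
  repeat {
    v <- array(stats::runif(prod(dim3)) < p, dim3)
    if (any(v)) return(binary_mask(v, spacing = spacing))
  }
}

# random small discretized ROI built from a random image/mask pair
random_roi <- function(dim3, n_levels = 3, p = 0.7) {
  m <- random_mask(dim3, p)
  img <- image_volume(array(stats::runif(prod(dim3), 0, n_levels * 25 - 0.1),
                            dim3))
  discretize(img, m, bin_width = 25)
}

# --- surface oracle ---------------------------------------------------------

# all foreground voxels with a 6-neighbor outside the foreground, as mm points
oracle_surface <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  pts <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!v[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    is_surf <- FALSE
    for (n in nb) {
      if (any(n < 1) || n[1] > d[1] || n[2] > d[2] || n[3] > d[3] ||
          !v[n[1], n[2], n[3]]) { is_surf <- TRUE; break }
    }
    if (is_surf)
      pts <- rbind(pts, (c(i, j, k) - 1) * mask$spacing + mask$origin)
  }
  pts
}

# double-loop directed max distance
oracle_directed_max <- function(A, B) {
  worst <- 0
  for (a in seq_len(nrow(A))) {
    best <- Inf
    for (b in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[a, ] - B[b, ])^2)))
    worst <- max(worst, best)
  }
  worst
}

oracle_surface_dice <- function(A, B, tau) {
  sa <- oracle_surface(A); sb <- oracle_surface(B)
  hits <- 0
  for (a in seq_len(nrow(sa))) {
    best <- Inf
    for (b in seq_len(nrow(sb))) best <- min(best, sqrt(sum((sa[a, ] - sb[b, ])^2)))
    if (best <= tau) hits <- hits + 1
  }
  for (b in seq_len(nrow(sb))) {
    best <- Inf
    for (a in seq_len(nrow(sa))) best <- min(best, sqrt(sum((sa[a, ] - sb[b, ])^2)))
    if (best <= tau) hits <- hits + 1
  }
  hits / (nrow(sa) + nrow(sb))
}

# --- texture-matrix oracles -------------------------------------------------

oracle_directions <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

roi_cells <- function(lv) which(lv > 0, arr.ind = TRUE)

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric co-occurrence counts per direction
oracle_glcm <- function(lv, ng) {
  d <- dim(lv)
  out <- array(0, c(ng, ng, 13))
  cells <- roi_cells(lv)
  for (r in seq_len(nrow(cells))) {
    p <- cells[r, ]
    for (k in 1:13) {
      q <- p + oracle_directions[k, ]
      if (!in_grid(q, d)) next
      lq <- lv[q[1], q[2], q[3]]
      if (lq == 0) next
      lp <- lv[p[1], p[2], p[3]]
      out[lp, lq, k] <- out[lp, lq, k] + 1
      out[lq, lp, k] <- out[lq, lp, k] + 1
    }
  }
  out
}

# run-length counts per direction by walking every maximal run
oracle_glrlm <- function(lv, ng) {
  d <- dim(lv)
  maxrun <- max(d)
  out <- array(0, c(ng, maxrun, 13))
  cells <- roi_cells(lv)
  for (k in 1:13) {
    dir <- oracle_directions[k, ]
    for (r in seq_len(nrow(cells))) {
      p <- cells[r, ]
      g <- lv[p[1], p[2], p[3]]
      prev <- p - dir
      if (in_grid(prev, d) && lv[prev[1], prev[2], prev[3]] == g) next
      len <- 1
      q <- p + dir
      while (in_grid(q, d) && lv[q[1], q[2], q[3]] == g) {
        len <- len + 1
        q <- q + dir
      }
      out[g, len, k] <- out[g, len, k] + 1
    }
  }
  out
}

neighbors26 <- function(p) {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- rbind(out, p + c(dx, dy, dz))
  }
  out
}

oracle_gldm <- function(lv, ng, alpha = 0) {
  d <- dim(lv)
  out <- matrix(0, ng, 27)
  cells <- roi_cells(lv)
  for (r in seq_len(nrow(cells))) {
    p <- cells[r, ]
    g <- lv[p[1], p[2], p[3]]
    dep <- 0
    nb <- neighbors26(p)
    for (n in seq_len(nrow(nb))) {
      q <- nb[n, ]
      if (!in_grid(q, d)) next
      lq <- lv[q[1], q[2], q[3]]
      if (lq > 0 && abs(lq - g) <= alpha) dep <- dep + 1
    }
    out[g, dep + 1] <- out[g, dep + 1] + 1
  }
  out
}

oracle_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  s <- numeric(ng); n <- numeric(ng)
  cells <- roi_cells(lv)
  for (r in seq_len(nrow(cells))) {
    p <- cells[r, ]
    g <- lv[p[1], p[2], p[3]]
    vals <- NULL
    nb <- neighbors26(p)
    for (m in seq_len(nrow(nb))) {
      q <- nb[m, ]
      if (!in_grid(q, d)) next
      lq <- lv[q[1], q[2], q[3]]
      if (lq > 0) vals <- c(vals, lq)
    }
    if (length(vals)) {
      s[g] <- s[g] + abs(g - mean(vals))
      n[g] <- n[g] + 1
    }
  }
  list(s = s, n = n)
}

# 26-connected zones of equal gray level, grown by naive flooding
oracle_glszm_zones <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- NULL
  cells <- roi_cells(lv)
  for (r in seq_len(nrow(cells))) {
    p <- cells[r, ]
    if (seen[p[1], p[2], p[3]]) next
    g <- lv[p[1], p[2], p[3]]
    stack <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    size <- 0
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      nb <- neighbors26(cur)
      for (n in seq_len(nrow(nb))) {
        q <- nb[n, ]
        if (!in_grid(q, d) || seen[q[1], q[2], q[3]]) next
        if (lv[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones <- rbind(zones, data.frame(level = g, size = size))
  }
  zones
}

# --- survival oracles -------------------------------------------------------

# classic two-sample log-rank: observed minus expected over event times
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d_t * n1 / n
    if (n > 1)
      V <- V + d_t * (n1 / n) * (1 - n1 / n) * (n - d_t) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(statistic = chisq,
       p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# negative log partial likelihood (Breslow; equals Efron when event times
# are unique), for an optim()-based reference Cox fit
oracle_cox_fit <- function(X, time, event) {
  X <- as.matrix(X)
  negll <- function(beta) {
    lp <- as.vector(X %*% beta)
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + lp[i] - log(sum(exp(lp[risk])))
    }
    -ll
  }
  stats::optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))$par
}
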