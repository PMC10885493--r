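# Independent brute-force oracles, written as plain enumerations so they
# share no code path with the package internals.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# direction-averaged symmetric GLCM by explicit pair enumeration
oracle_glcm_matrix <- function(lev, ng) {
  dm <- dim(lev)
  acc <- matrix(0, ng, ng)
  nvalid <- 0
  for (d in seq_len(nrow(oracle_dirs))) {
    off <- oracle_dirs[d, ]
    p <- matrix(0, ng, ng)
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      a <- lev[x, y, z]
      if (a == 0) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > dm[1] || y2 < 1 || y2 > dm[2] ||
          z2 < 1 || z2 > dm[3]) next
      b <- lev[x2, y2, z2]
      if (b == 0) next
      p[a, b] <- p[a, b] + 1
      p[b, a] <- p[b, a] + 1
    }
    if (sum(p) > 0) {
      acc <- acc + p / sum(p)
      nvalid <- nvalid + 1
    }
  }
  acc / nvalid
}

neighbors26 <- function(x, y, z, dm) {
  out <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
    if (x2 >= 1 && x2 <= dm[1] && y2 >= 1 && y2 <= dm[2] &&
        z2 >= 1 && z2 <= dm[3])
      out <- rbind(out, c(x2, y2, z2))
  }
  out
}

# 26-connected equal-level zones by plain repeated-sweep flood fill
oracle_zones <- function(lev) {
  dm <- dim(lev)
  lab <- array(0L, dm)
  nxt <- 0L
  coords <- which(lev != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, ]
    if (lab[v[1], v[2], v[3]] != 0) next
    nxt <- nxt + 1L
    g <- lev[v[1], v[2], v[3]]
    front <- matrix(v, 1)
    lab[v[1], v[2], v[3]] <- nxt
    while (nrow(front) > 0) {
      nf <- NULL
      for (k in seq_len(nrow(front))) {
        nb <- neighbors26(front[k, 1], front[k, 2], front[k, 3], dm)
        for (m in seq_len(nrow(nb))) {
          w <- nb[m, ]
          if (lev[w[1], w[2], w[3]] == g && lab[w[1], w[2], w[3]] == 0) {
            lab[w[1], w[2], w[3]] <- nxt
            nf <- rbind(nf, w)
          }
        }
      }
      front <- if (is.null(nf)) matrix(numeric(0), 0, 3) else nf
    }
  }
  lab
}

# distance to mask border by iterated 26-neighbourhood erosion
oracle_border_distance <- function(lev) {
  dm <- dim(lev)
  inm <- lev != 0
  dist <- array(0L, dm)
  cur <- inm
  d <- 0L
  while (any(cur)) {
    d <- d + 1L
    nxt <- array(FALSE, dm)
    coords <- which(cur, arr.ind = TRUE)
    for (r in seq_len(nrow(coords))) {
      v <- coords[r, ]
      nb <- neighbors26(v[1], v[2], v[3], dm)
      survives <- nrow(nb) == 26  # touching the grid edge is a border
      if (survives) {
        for (m in seq_len(nrow(nb)))
          if (!cur[nb[m, 1], nb[m, 2], nb[m, 3]]) { survives <- FALSE; break }
      }
      if (!survives) dist[v[1], v[2], v[3]] <- d
      nxt[v[1], v[2], v[3]] <- survives
    }
    cur <- nxt
  }
  dist
}

oracle_dependence <- function(lev) {
  dm <- dim(lev)
  dep <- array(-1L, dm)
  coords <- which(lev != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, ]
    g <- lev[v[1], v[2], v[3]]
    nb <- neighbors26(v[1], v[2], v[3], dm)
    k <- 0L
    for (m in seq_len(nrow(nb)))
      if (lev[nb[m, 1], nb[m, 2], nb[m, 3]] == g) k <- k + 1L
    dep[v[1], v[2], v[3]] <- k
  }
  dep
}

# Harrell's C by exhaustive pair enumeration
oracle_cindex <- function(lp, time, event) {
  n <- length(lp)
  conc <- 0; ties <- 0; usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] <= time[j]) { a <- i; b <- j } else { a <- j; b <- i }
    if (time[a] == time[b]) {
      if (event[a] + event[b] != 1) next
      ev <- if (event[a] == 1) a else b
      ot <- if (ev == a) b else a
      usable <- usable + 1
      if (lp[ev] > lp[ot]) conc <- conc + 1
      else if (lp[ev] == lp[ot]) ties <- ties + 1
    } else {
      if (event[a] != 1) next
      usable <- usable + 1
      if (lp[a] > lp[b]) conc <- conc + 1
      else if (lp[a] == lp[b]) ties <- ties + 1
    }
  }
  (conc + 0.5 * ties) / usable
}

# unpenalized Cox partial-likelihood Newton-Raphson (Breslow ties)
oracle_cox_newton <- function(x, time, event, tol = 1e-10, maxit = 100) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  dtimes <- sort(unique(time[event == 1]))
  for (it in 1:maxit) {
    grad <- rep(0, p); hess <- matrix(0, p, p)
    for (t0 in dtimes) {
      dead <- which(time == t0 & event == 1)
      risk <- which(time >= t0)
      eta <- exp(x[risk, , drop = FALSE] %*% beta)
      s0 <- sum(eta)
      s1 <- colSums(x[risk, , drop = FALSE] * as.vector(eta))
      s2 <- t(x[risk, , drop = FALSE]) %*%
        (x[risk, , drop = FALSE] * as.vector(eta))
      d <- length(dead)
      grad <- grad + colSums(x[dead, , drop = FALSE]) - d * s1 / s0
      hess <- hess + d * (s2 / s0 - (s1 %*% t(s1)) / s0^2)
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Cox log partial likelihood (Breslow) for grid-search oracles
oracle_cox_loglik <- function(beta, x, time, event) {
  x <- as.matrix(x)
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    dead <- which(time == t0 & event == 1)
    risk <- which(time >= t0)
    lp <- x %*% beta
    ll <- ll + sum(lp[dead]) - length(dead) * log(sum(exp(lp[risk])))
  }
  ll
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
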