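# Independent free-energy oracle for tiny bead systems.
#
# Rebuilds everything from scratch with naive loops: pairwise-spring
# Hessian, eigendecomposition, per-mode neighbour stiffness by explicit
# double loop, and the per-mode free energy as the log-ratio of Gaussian
# normalization integrals evaluated by numerical quadrature (integrate()),
# never via the closed-form log of the stiffness ratio.

# springs: data.frame(i, j, k); rest lengths at the observed geometry
oracle_springs <- function(xyz, cutoff = 11, base_k = 1) {
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff)
      out[[length(out) + 1]] <- data.frame(i = i, j = j, k = base_k)
  }
  do.call(rbind, out)
}

oracle_up_down <- function(springs, m, alpha) {
  hit <- springs$i == m | springs$j == m
  springs$k[hit] <- springs$k[hit] * alpha
  springs
}

oracle_binding <- function(springs, xyz, members, alpha, base_k = 1,
                           pair_cutoff = 15) {
  for (a in seq_along(members)) for (b in seq_along(members)) {
    if (a >= b) next
    i <- min(members[a], members[b]); j <- max(members[a], members[b])
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r > pair_cutoff) next
    at <- which(springs$i == i & springs$j == j)
    if (length(at) == 1) springs$k[at] <- springs$k[at] * alpha
    else springs <- rbind(springs, data.frame(i = i, j = j, k = alpha * base_k))
  }
  springs
}

oracle_hessian <- function(xyz, springs) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(springs))) {
    i <- springs$i[r]; j <- springs$j[r]
    d <- xyz[j, ] - xyz[i, ]
    u <- d / sqrt(sum(d^2))
    blk <- springs$k[r] * (u %o% u)
    ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}

oracle_epsilon <- function(H, neighbours) {
  n <- length(neighbours)
  eig <- eigen(H, symmetric = TRUE)
  lam <- rev(eig$values)
  vec <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  internal <- which(lam > 1e-12 * max(lam))
  eps <- matrix(0, length(internal), n)
  for (mi in seq_along(internal)) {
    e <- vec[, internal[mi]]
    for (i in seq_len(n)) {
      ei <- e[3 * (i - 1) + 1:3]
      for (j in neighbours[[i]]) {
        ej <- e[3 * (j - 1) + 1:3]
        eps[mi, i] <- eps[mi, i] + sum((ei - ej)^2)
      }
    }
  }
  eps
}

oracle_neighbours <- function(springs, n) {
  nb <- vector("list", n)
  for (r in seq_len(nrow(springs))) {
    nb[[springs$i[r]]] <- c(nb[[springs$i[r]]], springs$j[r])
    nb[[springs$j[r]]] <- c(nb[[springs$j[r]]], springs$i[r])
  }
  nb
}

# Delta g in kT units: -ln of the ratio of quadrature-evaluated Gaussian
# normalizations per mode, summed over paired mode ranks.
oracle_delta_g <- function(xyz, springs0, springsP, cutoff = 11,
                           floor = 1e-12) {
  n <- nrow(xyz)
  nb <- oracle_neighbours(springs0, n)   # unperturbed topology, both states
  eps0 <- oracle_epsilon(oracle_hessian(xyz, springs0), nb)
  epsP <- oracle_epsilon(oracle_hessian(xyz, springsP), nb)
  stopifnot(nrow(eps0) == nrow(epsP))
  z <- function(eps) stats::integrate(function(s) exp(-0.5 * eps * s^2),
                                      -Inf, Inf, rel.tol = 1e-12)$value
  dg <- numeric(n)
  for (i in seq_len(n)) {
    a <- eps0[, i]; b <- epsP[, i]
    ok <- a > 0 & b > 0 & a >= floor * max(a) & b >= floor * max(b)
    dg[i] <- -sum(vapply(which(ok), function(m) log(z(b[m]) / z(a[m])), 0))
  }
  dg
}
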