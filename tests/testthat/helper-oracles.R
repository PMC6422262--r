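# Independent oracles: plain-R brute force implementations used to pin down
# expected values. They deliberately share no code with the package internals.

# O(N^2) double-loop colonization rates
naive_colonization <- function(p, f, D, cc, boundary = "absorbing",
                               cutoff = 10, kernel_norm = TRUE) {
  nr <- nrow(p); nc <- ncol(p)
  out <- matrix(0, nr, nc)
  norm <- if (kernel_norm) 1 / (2 * pi * D^2) else 1
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      if (a == i && b == j) next
      if (p[a, b] == 0) next
      da <- abs(a - i); db <- abs(b - j)
      if (boundary == "periodic") {
        da <- min(da, nr - da); db <- min(db, nc - db)
      }
      d <- sqrt(da^2 + db^2)
      if (d > cutoff * D) next
      s <- s + f[a, b] * exp(-d / D)
    }
    out[i, j] <- cc * s * norm
  }
  out
}

# exact Markov transition matrix of the synchronous SPOM on a 1 x n row of
# cells (states indexed 1 + sum(p_i 2^(i-1)))
markov_matrix_1d <- function(f, D, e, cc, dt) {
  n <- length(f)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  ns <- nrow(states)
  P <- matrix(0, ns, ns)
  pe <- 1 - exp(-(e / f) * dt)
  for (s in seq_len(ns)) {
    p <- states[s, ]
    pc <- vapply(seq_len(n), function(i) {
      C <- cc * sum(vapply(setdiff(seq_len(n), i), function(j)
        p[j] * f[j] * exp(-abs(i - j) / D), numeric(1))) / (2 * pi * D^2)
      1 - exp(-C * dt)
    }, numeric(1))
    for (t in seq_len(ns)) {
      q <- states[t, ]
      pr <- 1
      for (i in seq_len(n)) {
        pr <- pr * if (p[i] == 1) {
          if (q[i] == 1) 1 - pe[i] else pe[i]
        } else {
          if (q[i] == 1) pc[i] else 1 - pc[i]
        }
      }
      P[s, t] <- pr
    }
  }
  list(P = P, states = states)
}

state_index <- function(p) 1L + sum(p * 2^(seq_along(p) - 1L))

# exact truncated-lattice kernel sum at cell (i0, j0) of an nr x nc grid
lattice_kernel_sum <- function(nr, nc, i0, j0, D, cutoff = 10,
                               kernel_norm = TRUE) {
  s <- 0
  for (a in seq_len(nr)) for (b in seq_len(nc)) {
    if (a == i0 && b == j0) next
    d <- sqrt((a - i0)^2 + (b - j0)^2)
    if (d > cutoff * D) next
    s <- s + exp(-d / D)
  }
  if (kernel_norm) s / (2 * pi * D^2) else s
}

# brute-force histogram of elevations over equal-width bins (right-open, last
# closed), as cell counts
brute_bin_counts <- function(z, n_bins) {
  rng <- range(z)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- integer(n_bins)
  for (v in z) {
    k <- n_bins
    for (b in seq_len(n_bins - 1)) {
      if (v >= edges[b] && v < edges[b + 1]) {
        k <- b
        break
      }
    }
    counts[k] <- counts[k] + 1L
  }
  counts
}
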