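# Independent brute-force oracles and shared fixtures for the test suite.
# The oracles deliberately use different computational routes than the
# package (direct sign-pattern expansion and pairwise comparison counting vs
# the package's rank-sum count accumulation).

# Signed-rank exact p by direct expansion of all 2^n sign patterns.
oracle_signrank_p <- function(x, y, sidedness = "two") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  wnull <- apply(signs, 1, function(s) sum(r[s]))
  N <- length(wnull)
  ge <- sum(wnull >= w_obs - 1e-9)
  le <- sum(wnull <= w_obs + 1e-9)
  if (sidedness == "two") min(2 * min(ge, le), N) / N else min(ge, le) / N
}

# Mann-Whitney exact p by subset enumeration with U computed from direct
# pairwise comparisons (not rank sums).
oracle_mw_p <- function(a, b, sidedness = "two") {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(a, b)
  na <- length(a)
  u_obs <- u_of(a, b)
  subsets <- utils::combn(length(pooled), na)
  unull <- apply(subsets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  N <- length(unull)
  ge <- sum(unull >= u_obs - 1e-9)
  le <- sum(unull <= u_obs + 1e-9)
  if (sidedness == "two") min(2 * min(ge, le), N) / N else min(ge, le) / N
}

# Small, fast phantom used where full-size geometry is not the point.
small_phantom_config <- function(sigma = 0, ...) {
  phantom_config(dims = c(16, 16, 4), tumour_centre = c(12, 8, 2),
                 tumour_radius = 2.2, artery_corner = c(7, 3, 1),
                 artery_size = c(2, 2, 4), n_frames = 50, sigma = sigma, ...)
}

# All permutations of 1..n (for the Pearson permutation-null oracle).
combinat_perms <- function(n) {
  if (n == 1) return(list(1))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

# Per-voxel concentration curves for all voxels of a mask (noise-free path
# used by several AIF and kinetics tests).
phantom_conc_matrix <- function(ph, mask, baseline = 2, r1 = 3.7) {
  vox <- which(mask$data > 0)
  d <- dim(ph$series$data)
  nvox <- prod(d[1:3])
  nt <- d[4]
  t(vapply(vox, function(v) {
    s <- ph$series$data[v + (seq_len(nt) - 1) * nvox]
    signal_to_concentration(s, baseline,
                            relaxation_state(ph$t10$data[v], 1, r1),
                            ph$series$tr, ph$series$flip_angle)$conc
  }, numeric(nt)))
}
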