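# Independent brute-force oracles and small fixture builders shared by the
# test files. These deliberately avoid the package's own vectorized code
# paths: the moving-average oracle loops over windows, the MCC oracle
# expands the confusion matrix into label vectors, and the superposition
# oracle searches rotation space directly.

# uniform random points on the 3-state probability simplex
rand_simplex <- function(n) {
  g <- matrix(stats::rexp(3 * n), ncol = 3)
  g / rowSums(g)
}

make_profile <- function(p, id = "test", source = "synthetic") {
  ss_profile(
    tibble::tibble(position = seq_len(nrow(p)), residue = "X",
                   p_h = p[, 1], p_e = p[, 2], p_c = p[, 3]),
    identifier = id, source = source)
}

# profile whose DI trace is (approximately) a prescribed vector, built by
# inverting the index along the simplex edge path
profile_with_di <- function(di, id = "test") {
  p <- t(vapply(di, di_target_point, numeric(3)))
  make_profile(p, id)
}

# windowed-mean maximum by explicit enumeration of every window
brute_force_wmax <- function(di, cr, terminal_exclude = 0) {
  lo <- terminal_exclude + 1
  hi <- length(di) - terminal_exclude
  starts <- lo:(hi - cr + 1)
  max(vapply(starts, function(s) mean(di[s:(s + cr - 1)]), numeric(1)))
}

# MCC as the Pearson correlation of the expanded binary truth/prediction
# vectors (valid whenever all four marginals are nonzero)
pearson_mcc <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  stats::cor(truth, pred)
}

rmsd_at_rotation <- function(q, a, b) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
}

# minimum RMSD over rotations by random quaternion sampling followed by
# Nelder-Mead polish of the best few candidates; uses only direct RMSD
# evaluations, never the Kabsch solution
brute_force_rmsd <- function(a, b, n_samples = 20000) {
  qs <- matrix(stats::rnorm(4 * n_samples), ncol = 4)
  vals <- apply(qs, 1, rmsd_at_rotation, a = a, b = b)
  best <- order(vals)[1:5]
  polished <- vapply(best, function(i) {
    stats::optim(qs[i, ], rmsd_at_rotation, a = a, b = b,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1))
  min(polished)
}

rigid_motion <- function(xyz, angle = 0.6, axis = c(0, 0, 1),
                         shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  q <- c(cos(angle / 2), sin(angle / 2) * axis)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  xyz %*% t(R) + matrix(rep(shift, each = nrow(xyz)), ncol = 3)
}
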