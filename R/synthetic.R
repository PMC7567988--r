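#' Simplex point with a prescribed diversity index
#'
#' Inverts the diversity index along the edge-to-center path of the
#' probability simplex: for a target `d` in `[1, 2]` the point
#' `(p, 1 - p, 0)` with `p = (1 + sqrt(2/d - 1)) / 2`, and for `d` in
#' `(2, 3]` the point `(p, p, 1 - 2p)` with `p = (2 + sqrt(6/d - 2)) / 6`.
#' The path is continuous at `d = 2` and reaches the uniform distribution at
#' `d = 3`, giving a closed-form map from a target index to a probability
#' row.
#'
#' @param d Target diversity index in `[1, 3]`.
#' @return A 3-vector on the probability simplex whose
#'   [diversity_index()] equals `d`.
#' @export
di_target_point <- function(d) {
  stopifnot(length(d) == 1, d >= 1, d <= 3)
  if (d <= 2) {
    p <- (1 + sqrt(2 / d - 1)) / 2
    c(p, 1 - p, 0)
  } else {
    p <- (2 + sqrt(6 / d - 2)) / 6
    c(p, p, 1 - 2 * p)
  }
}

# one Dirichlet draw centered on a target simplex point; concentration Inf
# returns the target exactly, and zero components stay exactly zero
dirichlet_row <- function(target, concentration) {
  if (!is.finite(concentration)) return(target)
  g <- stats::rgamma(length(target), shape = concentration * target)
  if (sum(g) == 0) return(target)
  g / sum(g)
}

generate_profile <- function(id, len, mono_confidence, noise_scale,
                             segment = NULL, segment_margin = 5) {
  states <- matrix(0, nrow = len, ncol = 3)
  # background: runs of a dominant secondary-structure state with a 50/50
  # two-state jump row at each run boundary, as real predictors produce at
  # element boundaries; jump rows are part of the noise model and are
  # disabled along with the jitter when noise_scale is infinite
  pos <- 1L
  prev_state <- 0L
  while (pos <= len) {
    run_len <- min(sample(4:15, 1), len - pos + 1L)
    state <- sample(setdiff(1:3, prev_state), 1)
    target <- rep((1 - mono_confidence) / 2, 3)
    target[state] <- mono_confidence
    for (i in pos:(pos + run_len - 1L)) {
      states[i, ] <- dirichlet_row(target, noise_scale)
    }
    if (prev_state != 0L && is.finite(noise_scale)) {
      jump <- rep(0, 3)
      jump[c(state, prev_state)] <- 0.5
      states[pos, ] <- dirichlet_row(jump, noise_scale)
    }
    prev_state <- state
    pos <- pos + run_len
  }
  if (!is.null(segment)) {
    target <- di_target_point(segment$di)[sample(3)]
    start <- sample(seq(segment_margin + 1L,
                        len - segment_margin - segment$length + 1L), 1)
    for (i in start:(start + segment$length - 1L)) {
      states[i, ] <- dirichlet_row(target, noise_scale)
    }
  }
  ss_profile(
    tibble::tibble(
      position = seq_len(len),
      residue = sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       len, replace = TRUE),
      p_h = states[, 1], p_e = states[, 2], p_c = states[, 3]),
    identifier = id, source = "synthetic")
}

#' Generate a labeled synthetic profile dataset
#'
#' Emulates the qualitative structure of real secondary-structure
#' predictions so the whole classification pipeline can be exercised
#' without running a predictor. Monomorphic profiles are confident
#' everywhere: runs of a dominant state at probability `mono_confidence`,
#' with single-row 50/50 jumps at run boundaries, so the raw diversity index
#' spikes briefly but the moving average stays low. Metamorphic profiles add
#' one contiguous segment of `meta_segment_length` residues whose rows sit
#' near the simplex point with diversity index `meta_segment_di` (see
#' [di_target_point()]), mimicking a fold-switching region the predictor
#' cannot resolve. Row-level jitter is Dirichlet noise with concentration
#' `noise_scale` around each target point (`Inf` disables jitter). Output is
#' deterministic for a fixed seed.
#'
#' @param n_metamorphic,n_monomorphic Number of sequences per class.
#' @param length_range Inclusive range of sequence lengths in residues.
#' @param mono_confidence Dominant-state probability of background rows.
#' @param meta_segment_length Length of the elevated-uncertainty segment.
#' @param meta_segment_di Target mean diversity index of the segment,
#'   in `(1, 3]`.
#' @param noise_scale Dirichlet concentration of row jitter; larger is
#'   quieter, `Inf` places every row exactly on its target.
#' @param segment_margin Minimum distance of the segment from either
#'   terminus, matching the default terminal exclusion of the classifier.
#' @param seed Integer seed; identical arguments give identical datasets.
#' @return A labeled dataset tibble (see [labeled_dataset()]) with
#'   `n_metamorphic + n_monomorphic` rows.
#' @export
generate_dataset <- function(n_metamorphic = 50,
                             n_monomorphic = 50,
                             length_range = c(60, 120),
                             mono_confidence = 0.95,
                             meta_segment_length = 20,
                             meta_segment_di = 2.8,
                             noise_scale = 200,
                             segment_margin = 5,
                             seed = 1L) {
  stopifnot(n_metamorphic >= 0, n_monomorphic >= 0,
            length(length_range) == 2, length_range[1] <= length_range[2],
            mono_confidence > 1 / 3, mono_confidence <= 1,
            meta_segment_length >= 1,
            meta_segment_di > 1, meta_segment_di <= 3,
            noise_scale > 0)
  if (length_range[1] < meta_segment_length + 2 * segment_margin &&
      n_metamorphic > 0) {
    rlang::abort(sprintf(
      "minimum sequence length %d cannot hold a %d-residue segment with %d-residue margins",
      length_range[1], meta_segment_length, segment_margin))
  }
  withr::with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]),
                   n_metamorphic + n_monomorphic, replace = TRUE)
    profiles <- vector("list", n_metamorphic + n_monomorphic)
    labels <- character(n_metamorphic + n_monomorphic)
    for (i in seq_len(n_metamorphic)) {
      profiles[[i]] <- generate_profile(
        sprintf("meta_%03d", i), lens[i], mono_confidence, noise_scale,
        segment = list(length = meta_segment_length, di = meta_segment_di),
        segment_margin = segment_margin)
      labels[i] <- "metamorphic"
    }
    for (j in seq_len(n_monomorphic)) {
      i <- n_metamorphic + j
      profiles[[i]] <- generate_profile(
        sprintf("mono_%03d", j), lens[i], mono_confidence, noise_scale)
      labels[i] <- "monomorphic"
    }
    labeled_dataset(profiles, labels)
  })
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

make_pair <- function(ids, ss, xyz, i, j) {
  list(parent_id = ids[i], child_id = ids[j],
       aligned_ss_a = ss[i], aligned_ss_b = ss[j],
       ca_a = xyz[[i]], ca_b = xyz[[j]])
}

#' Generate a synthetic parent/children structure cluster for curation tests
#'
#' Builds toy C-alpha coordinate sets and three-state secondary-structure
#' strings for one parent structure and its children, in two flavors.
#' `"monomorphic_like"` children are rigid motions of the parent with
#' sub-angstrom jitter and near-identical secondary structure, so every pair
#' passes the structural screen (RMSD < 2.4 angstroms, mismatch score <= 9).
#' `"kaib_like"` clusters contain one fold-switched child: a 14-residue
#' helix-to-strand conversion (mismatch score 28) and large non-rigid
#' coordinate displacements (superposed RMSD well above 7 angstroms), so the
#' screen must drop the parent. Deterministic for a fixed seed.
#'
#' @param kind `"kaib_like"` or `"monomorphic_like"`.
#' @param seed Integer seed.
#' @param n_children Number of child structures (default 4).
#' @param length Number of residues (default 60).
#' @return A list of structure-pair records over all pairs in the cluster,
#'   each suitable for [monomorphic_structure_filter()].
#' @export
generate_curation_cluster <- function(kind = c("kaib_like", "monomorphic_like"),
                                      seed = 1L, n_children = 4, length = 60) {
  kind <- match.arg(kind)
  stopifnot(n_children >= 1, length >= 40)
  withr::with_seed(seed, {
    steps <- matrix(stats::rnorm(length * 3), ncol = 3)
    steps <- 3.8 * steps / sqrt(rowSums(steps^2))
    parent_xyz <- apply(steps, 2, cumsum)
    blocks <- c(rep("H", 20), rep("C", 10), rep("E", 15),
                rep("C", length - 45))
    parent_ss <- paste(blocks, collapse = "")
    ids <- c("parent", sprintf("child_%d", seq_len(n_children)))
    xyz <- vector("list", n_children + 1)
    ss <- character(n_children + 1)
    xyz[[1]] <- parent_xyz
    ss[1] <- parent_ss
    for (ch in seq_len(n_children)) {
      is_switcher <- kind == "kaib_like" && ch == 1
      if (is_switcher) {
        # non-rigid displacement: cannot be superposed away
        child_xyz <- parent_xyz + matrix(stats::rnorm(length * 3, sd = 8),
                                         ncol = 3)
        chars <- strsplit(parent_ss, "")[[1]]
        chars[3:16] <- "E"  # helix block switched to strand
        child_ss <- paste(chars, collapse = "")
      } else {
        child_xyz <- (parent_xyz +
                        matrix(stats::rnorm(length * 3, sd = 0.05),
                               ncol = 3)) %*% random_rotation() +
          matrix(rep(stats::rnorm(3, sd = 10), each = length), ncol = 3)
        chars <- strsplit(parent_ss, "")[[1]]
        flip <- sample(seq_len(length), 2)
        chars[flip] <- "C"  # minor edge-of-element disagreement, cost <= 2
        child_ss <- paste(chars, collapse = "")
      }
      xyz[[ch + 1]] <- child_xyz
      ss[ch + 1] <- child_ss
    }
    pairs <- list()
    for (i in seq_len(n_children)) {
      for (j in (i + 1):(n_children + 1)) {
        pairs[[length(pairs) + 1]] <- make_pair(ids, ss, xyz, i, j)
      }
    }
    pairs
  })
}
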