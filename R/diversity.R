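#' Per-residue diversity index of a three-state probability distribution
#'
#' The diversity index is the reciprocal of the Simpson/Herfindahl
#' concentration of the helix/strand/coil probability distribution at one
#' residue:
#' \deqn{DI = (P(H)^2 + P(E)^2 + P(C)^2)^{-1}.}
#' It ranges from 1 (all mass on one state, confident prediction) to 3
#' (uniform over the three states, maximal uncertainty), and coincides with
#' the exponentiated Shannon entropy at those two limits. Elevated values
#' flag residues whose secondary structure the predictor cannot pin down —
#' the signal exploited to detect fold-switching regions.
#'
#' @param p_h,p_e,p_c Numeric vectors of helix, strand and coil
#'   probabilities. Recycled to a common length; each triple must be
#'   non-negative and sum to 1 within `tol`.
#' @param tol Tolerance on the simplex constraint.
#' @return Numeric vector of diversity indices in `[1, 3]`.
#' @export
#' @examples
#' diversity_index(1, 0, 0)       # 1: fully confident
#' diversity_index(1/3, 1/3, 1/3) # 3: maximally uncertain
diversity_index <- function(p_h, p_e, p_c, tol = 1e-9) {
  n <- max(length(p_h), length(p_e), length(p_c))
  p_h <- rep_len(p_h, n); p_e <- rep_len(p_e, n); p_c <- rep_len(p_c, n)
  if (any(p_h < 0 | p_e < 0 | p_c < 0)) {
    rlang::abort("probabilities must be non-negative")
  }
  s <- p_h + p_e + p_c
  if (any(abs(s - 1) > tol)) {
    rlang::abort(sprintf("probabilities must sum to 1 within %g (worst deviation %g)",
                         tol, max(abs(s - 1))))
  }
  1 / (p_h^2 + p_e^2 + p_c^2)
}

#' Diversity-index trace of a profile
#'
#' Evaluates [diversity_index()] at every residue of a profile.
#'
#' @param profile An [ss_profile()].
#' @return A tibble of class `di_trace` with columns `position` and `di`;
#'   the sequence identifier is carried as an attribute.
#' @export
di_trace <- function(profile) {
  stopifnot(inherits(profile, "ss_profile"))
  out <- tibble::tibble(
    position = profile$position,
    di = diversity_index(profile$p_h, profile$p_e, profile$p_c)
  )
  structure(out,
            identifier = attr(profile, "identifier"),
            class = c("di_trace", class(out)))
}

#' Maximum moving average of a diversity-index trace
#'
#' Slides a window of `cr` consecutive residues over the trace and returns
#' the largest window mean. Residues within `terminal_exclude` positions of
#' either terminus are ignored entirely: every window lies within positions
#' `[terminal_exclude + 1, L - terminal_exclude]`. Secondary-structure
#' predictions at chain termini are systematically uncertain for reasons
#' unrelated to fold switching, which is why the flanks are dropped.
#'
#' @param di Numeric vector of per-residue diversity indices (or a
#'   `di_trace`, whose `di` column is used).
#' @param cr Window length in residues (the number of consecutive residues
#'   averaged).
#' @param terminal_exclude Number of residues ignored at each terminus.
#' @return The maximum window mean, a single number.
#' @export
max_moving_average <- function(di, cr, terminal_exclude = 0) {
  if (inherits(di, "di_trace")) di <- di$di
  stopifnot(is.numeric(di), length(cr) == 1, cr >= 1,
            length(terminal_exclude) == 1, terminal_exclude >= 0)
  cr <- as.integer(cr)
  terminal_exclude <- as.integer(terminal_exclude)
  L <- length(di)
  usable <- L - 2L * terminal_exclude
  if (usable < cr) {
    rlang::abort(sprintf(
      paste0("sequence too short: %d residues leave %d usable after excluding ",
             "%d at each terminus, but the window needs %d"),
      L, max(usable, 0L), terminal_exclude, cr))
  }
  x <- di[(terminal_exclude + 1L):(L - terminal_exclude)]
  cs <- cumsum(c(0, x))
  means <- (cs[(cr + 1L):(usable + 1L)] - cs[1L:(usable - cr + 1L)]) / cr
  max(means)
}

#' Classify a profile as metamorphic or monomorphic
#'
#' Computes the diversity-index trace, takes the maximum moving average over
#' windows of `cr` residues (excluding `terminal_exclude` residues at each
#' terminus), and calls the sequence metamorphic when that maximum strictly
#' exceeds `di_thre`. A window maximum exactly equal to the threshold is
#' monomorphic.
#'
#' @param profile An [ss_profile()].
#' @inheritParams max_moving_average
#' @param di_thre Decision threshold on the window maximum, in `[1, 3]`.
#' @return A one-row tibble with columns `identifier`, `window_max`, `label`
#'   (`"metamorphic"` or `"monomorphic"`).
#' @export
classify_profile <- function(profile, cr, di_thre, terminal_exclude = 5) {
  stopifnot(length(di_thre) == 1, di_thre >= 1, di_thre <= 3)
  wmax <- max_moving_average(di_trace(profile), cr, terminal_exclude)
  tibble::tibble(
    identifier = attr(profile, "identifier"),
    window_max = wmax,
    label = ifelse(wmax > di_thre, "metamorphic", "monomorphic")
  )
}

#' Plot a diversity-index trace
#'
#' Draws the per-residue diversity index with its moving average and,
#' optionally, the decision threshold — the standard diagnostic track for
#' locating candidate fold-switching regions.
#'
#' @param object A `di_trace` from [di_trace()].
#' @param cr Window length for the moving-average overlay.
#' @param di_thre Optional threshold drawn as a dashed line.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot di_trace
#' @export
autoplot.di_trace <- function(object, cr = 14, di_thre = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) >= cr) {
    mm <- stats::filter(df$di, rep(1 / cr, cr), sides = 1)
    df$moving_avg <- c(mm[-seq_len(cr - 1)], rep(NA_real_, cr - 1))
  } else {
    df$moving_avg <- NA_real_
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$di), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$moving_avg),
                       colour = "darkgreen", na.rm = TRUE) +
    ggplot2::labs(x = "residue position", y = "diversity index",
                  title = attr(object, "identifier")) +
    ggplot2::coord_cartesian(ylim = c(1, 3)) +
    ggplot2::theme_minimal()
  if (!is.null(di_thre)) {
    p <- p + ggplot2::geom_hline(yintercept = di_thre,
                                 linetype = "dashed", colour = "steelblue")
  }
  p
}
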