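#' Fit a two-descriptor linear discriminant by maximizing the MCC
#'
#' When two secondary-structure predictors each supply a per-sequence
#' window-maximum diversity index, a straight line in the `(di_a, di_b)`
#' plane can separate metamorphic from monomorphic sequences better than
#' either descriptor alone. The line is found by exhaustive search: its
#' normal direction sweeps `angles_deg` (degrees), and for each direction
#' every midpoint between consecutive projected points is tried as the
#' offset, in both orientations. This visits every distinct labeling a line
#' can induce on the sample (up to the angular resolution) and avoids the
#' vertical-line pathologies of a slope/intercept grid. Ties are broken by
#' the first candidate in scan order (angle, then offset, high-side
#' orientation first), so the fit is deterministic.
#'
#' @param points A data frame with columns `di_a`, `di_b` (per-sequence
#'   window-max diversity indices from two predictors) and `label`
#'   (`"metamorphic"` / `"monomorphic"`; both must be present).
#' @param angles_deg Integer vector of normal angles, in degrees, to sweep.
#' @return An object of class `di_discriminant`: the decision line as
#'   `a * di_a + b * di_b = offset` with unit normal `(a, b)` at
#'   `angle_deg`, its `slope` and `intercept` form (`NA` for a vertical
#'   line), `orientation` (`"high"` when the metamorphic side is
#'   `a * di_a + b * di_b > offset`), the achieved `mcc`, and the training
#'   `points`.
#' @export
fit_discriminant <- function(points, angles_deg = 0:179) {
  required <- c("di_a", "di_b", "label")
  if (!all(required %in% names(points))) {
    rlang::abort("points needs columns di_a, di_b, label")
  }
  truth <- points$label == "metamorphic"
  if (all(truth) || !any(truth)) {
    rlang::abort("both classes must be present to fit a discriminant")
  }
  P <- sum(truth); N <- sum(!truth)
  best <- list(mcc = -Inf)
  for (ang in angles_deg) {
    th <- ang * pi / 180
    a <- cos(th); b <- sin(th)
    s <- a * points$di_a + b * points$di_b
    o <- order(s)
    s_sorted <- s[o]
    t_sorted <- truth[o]
    u <- unique(s_sorted)
    if (length(u) < 2) {
      cand_mcc <- 0
      if (cand_mcc > best$mcc) {
        best <- list(mcc = 0, angle_deg = ang, a = a, b = b,
                     offset = u[1], orientation = "high")
      }
      next
    }
    # cumulative positives/negatives at or below each distinct value
    grp <- match(s_sorted, u)
    cum_p <- cumsum(as.numeric(rowsum(as.numeric(t_sorted), grp)))
    cum_n <- cumsum(as.numeric(rowsum(as.numeric(!t_sorted), grp)))
    cuts <- (u[-length(u)] + u[-1]) / 2
    below_p <- cum_p[-length(cum_p)]
    below_n <- cum_n[-length(cum_n)]
    # orientation "high": metamorphic side is s > cut
    m_high <- mcc(tp = P - below_p, fp = N - below_n,
                  tn = below_n, fn = below_p)
    m_low <- mcc(tp = below_p, fp = below_n,
                 tn = N - below_n, fn = P - below_p)
    for (orient in c("high", "low")) {
      m <- if (orient == "high") m_high else m_low
      i <- which.max(m)
      if (m[i] > best$mcc) {
        best <- list(mcc = m[i], angle_deg = ang, a = a, b = b,
                     offset = cuts[i], orientation = orient)
      }
    }
  }
  slope <- if (abs(best$b) < 1e-12) NA_real_ else -best$a / best$b
  intercept <- if (abs(best$b) < 1e-12) NA_real_ else best$offset / best$b
  structure(
    list(angle_deg = best$angle_deg, a = best$a, b = best$b,
         offset = best$offset, orientation = best$orientation,
         slope = slope, intercept = intercept, mcc = best$mcc,
         points = tibble::as_tibble(points)),
    class = "di_discriminant")
}

#' @export
print.di_discriminant <- function(x, ...) {
  cat(sprintf(
    "Linear discriminant: %.4f * di_a + %.4f * di_b %s %.4f -> metamorphic (MCC = %.3f)\n",
    x$a, x$b, if (x$orientation == "high") ">" else "<", x$offset, x$mcc))
  invisible(x)
}

#' @rdname fit_discriminant
#' @param x A `di_discriminant` object.
#' @param ... Ignored.
#' @method glance di_discriminant
#' @export
glance.di_discriminant <- function(x, ...) {
  tibble::tibble(angle_deg = x$angle_deg, slope = x$slope,
                 intercept = x$intercept, offset = x$offset,
                 orientation = x$orientation, mcc = x$mcc,
                 n = nrow(x$points))
}

#' Predict labels from a fitted discriminant
#'
#' @param object A `di_discriminant`.
#' @param newdata Data frame with columns `di_a`, `di_b`.
#' @param ... Ignored.
#' @return Character vector of labels.
#' @export
predict.di_discriminant <- function(object, newdata, ...) {
  s <- object$a * newdata$di_a + object$b * newdata$di_b
  high <- s > object$offset
  meta <- if (object$orientation == "high") high else !high
  ifelse(meta, "metamorphic", "monomorphic")
}

#' Plot a fitted two-descriptor discriminant
#'
#' Scatter of the training points in the `(di_a, di_b)` plane, colored by
#' true label and shaped by correctness, with the decision line overlaid.
#'
#' @param object A `di_discriminant`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot di_discriminant
#' @export
autoplot.di_discriminant <- function(object, ...) {
  pts <- object$points
  pts$predicted <- predict(object, pts)
  pts$correct <- pts$predicted == pts$label
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$di_a, y = .data$di_b,
                                         colour = .data$label,
                                         shape = .data$correct)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(metamorphic = "firebrick", monomorphic = "steelblue")) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "window-max DI (predictor A)",
                  y = "window-max DI (predictor B)") +
    ggplot2::theme_minimal()
  if (is.na(object$slope)) {
    p + ggplot2::geom_vline(xintercept = object$offset / object$a,
                            linetype = "dashed")
  } else {
    p + ggplot2::geom_abline(slope = object$slope,
                             intercept = object$intercept,
                             linetype = "dashed")
  }
}

#' Squared correlation between two diversity-index descriptors
#'
#' Ordinary least-squares R-squared (the squared Pearson correlation)
#' between per-sequence diversity indices obtained from two predictors;
#' a high value means the second descriptor adds little information.
#'
#' @param points Data frame with columns `di_a`, `di_b` (at least 3 rows,
#'   neither column constant).
#' @return R-squared, a single number in `[0, 1]`.
#' @export
descriptor_correlation <- function(points) {
  if (!all(c("di_a", "di_b") %in% names(points))) {
    rlang::abort("points needs columns di_a and di_b")
  }
  if (nrow(points) < 3) rlang::abort("at least 3 points are required")
  if (stats::sd(points$di_a) == 0 || stats::sd(points$di_b) == 0) {
    rlang::abort("R-squared undefined: a descriptor is constant")
  }
  stats::cor(points$di_a, points$di_b)^2
}
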