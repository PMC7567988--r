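# a small deterministic dataset separable by construction: metamorphic
# profiles carry a DI-3 segment, monomorphic ones are flat at DI ~1.1
toy_dataset <- function(n_per_class = 6, L = 60) {
  profiles <- list()
  labels <- character()
  for (i in seq_len(n_per_class)) {
    di <- rep(1.1, L)
    di[25:44] <- 3
    profiles[[length(profiles) + 1]] <-
      profile_with_di(di, sprintf("m%02d", i))
    labels <- c(labels, "metamorphic")
  }
  for (i in seq_len(n_per_class)) {
    profiles[[length(profiles) + 1]] <-
      profile_with_di(rep(1.1, L), sprintf("s%02d", i))
    labels <- c(labels, "monomorphic")
  }
  labeled_dataset(profiles, labels)
}

test_that("evaluate_dataset tallies classify outcomes against labels", {
  d <- toy_dataset(4)
  cm <- evaluate_dataset(d, cr = 15, di_thre = 2.1)
  expect_equal(cm, tibble::tibble(tp = 4, fp = 0, tn = 4, fn = 0))
  expect_equal(sum(cm), nrow(d))
  # DI is capped at 3 and the threshold is strict, so 3.0 classifies nothing
  cm3 <- evaluate_dataset(d, cr = 15, di_thre = 3.0)
  expect_equal(cm3$tp + cm3$fp, 0)
  # all-flat monomorphic dataset
  flat <- d[d$label == "monomorphic", ]
  cmf <- evaluate_dataset(flat, cr = 10, di_thre = 1.4)
  expect_equal(cmf, tibble::tibble(tp = 0, fp = 0, tn = 4, fn = 0))
})

test_that("profiles too short for the window raise an error naming them", {
  short <- labeled_dataset(
    list(profile_with_di(rep(1.2, 20), "shorty"),
         profile_with_di(rep(1.2, 80), "ok")),
    c("monomorphic", "monomorphic"))
  expect_error(evaluate_dataset(short, cr = 15, di_thre = 2, terminal_exclude = 5),
               "shorty")
})

test_that("grid search is exhaustive, tie-broken lexicographically, and matches per-cell re-evaluation", {
  d <- toy_dataset(5)
  crs <- c(6, 10, 15)
  thrs <- c(1.4, 2.0, 2.6)
  fit <- grid_search(d, cr_values = crs, di_thre_values = thrs)
  tab <- tidy(fit)
  expect_equal(nrow(tab), 9)
  # exhaustiveness oracle: re-evaluate every cell independently
  for (r in seq_len(nrow(tab))) {
    cm <- evaluate_dataset(d, tab$cr[r], tab$di_thre[r])
    expect_equal(unlist(tab[r, c("tp", "fp", "tn", "fn")]),
                 unlist(cm), ignore_attr = TRUE)
    expect_equal(tab$mcc[r], mcc(cm))
  }
  # the toy set is separable at every cell below DI 3, so ties abound and
  # the lexicographic rule must pick the smallest cr, then threshold
  expect_equal(fit$best_mcc, 1)
  expect_equal(fit$best_cr, 6L)
  expect_equal(fit$best_di_thre, 1.4)
  # single-cell grid returns that cell
  single <- grid_search(d, cr_values = 10, di_thre_values = 2.0)
  expect_equal(nrow(tidy(single)), 1)
  expect_equal(glance(single)$cr, 10L)
})

test_that("identical profiles with mixed labels give degenerate MCC 0 everywhere", {
  prof <- lapply(1:6, function(i) profile_with_di(rep(1.5, 50), paste0("p", i)))
  d <- labeled_dataset(prof, rep(c("metamorphic", "monomorphic"), 3))
  fit <- grid_search(d, cr_values = c(6, 10), di_thre_values = c(1.4, 2.0))
  expect_true(all(tidy(fit)$mcc == 0))
  expect_equal(fit$best_mcc, 0)
})

test_that("raising the threshold never decreases TN or FN (grid-wide)", {
  d <- generate_dataset(n_metamorphic = 10, n_monomorphic = 10,
                        meta_segment_di = 2.2, mono_confidence = 0.85,
                        seed = 13)
  fit <- grid_search(d)
  tab <- dplyr::arrange(tidy(fit), cr, di_thre)
  by_cr <- split(tab, tab$cr)
  for (sub in by_cr) {
    expect_true(all(diff(sub$tn) >= 0))
    expect_true(all(diff(sub$fn) >= 0))
  }
})

test_that("cross-validation partitions correctly and is seed-deterministic", {
  d <- toy_dataset(12)  # n = 24
  cv <- cross_validate(d, k = 6, cr_values = c(6, 10),
                       di_thre_values = c(1.4, 2.0), seed = 6)
  folds <- tidy(cv)
  expect_equal(nrow(folds), 6)
  expect_equal(folds$n_test, rep(4, 6))
  expect_equal(sum(folds$n_test), nrow(d))
  # every entry lands in exactly one test fold
  expect_equal(sum(folds$tp + folds$fp + folds$tn + folds$fn), nrow(d))
  # separable on every fold (all folds here hold both classes)
  stopifnot(all(folds$tp + folds$fn > 0), all(folds$tn + folds$fp > 0))
  expect_equal(glance(cv)$mean_test_mcc, 1)
  expect_equal(glance(cv)$sd_test_mcc, 0, tolerance = 1e-12)
  # determinism
  cv2 <- cross_validate(d, k = 6, cr_values = c(6, 10),
                        di_thre_values = c(1.4, 2.0), seed = 6)
  expect_identical(tidy(cv), tidy(cv2))
  # uneven n: first n mod k chunks take the extra entry
  d14 <- toy_dataset(7)
  cv14 <- cross_validate(d14, k = 4, cr_values = 10, di_thre_values = 2,
                         seed = 1)
  expect_equal(sort(tidy(cv14)$n_test, decreasing = TRUE), c(4, 4, 3, 3))
  expect_error(cross_validate(toy_dataset(2), k = 9), "exceeds")
})
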