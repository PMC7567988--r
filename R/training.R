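#' Assemble a labeled profile dataset
#'
#' A labeled dataset is a tibble with one row per sequence: `identifier`,
#' `profile` (a list-column of [ss_profile()] objects) and `label`
#' (`"metamorphic"` or `"monomorphic"`). Metamorphic is the positive class.
#'
#' @param profiles A list of [ss_profile()] objects.
#' @param labels Character vector of labels, one per profile.
#' @return A tibble with columns `identifier`, `profile`, `label`.
#' @export
labeled_dataset <- function(profiles, labels) {
  if (length(profiles) != length(labels)) {
    rlang::abort("profiles and labels must have the same length")
  }
  ok <- vapply(profiles, inherits, logical(1), what = "ss_profile")
  if (!all(ok)) rlang::abort("every profile must be an ss_profile")
  bad <- setdiff(unique(labels), c("metamorphic", "monomorphic"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  ids <- vapply(profiles, profile_id, character(1))
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicate identifier(s): ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble::tibble(identifier = ids, profile = profiles, label = labels)
}

check_dataset <- function(dataset, require_both_classes = FALSE) {
  required <- c("identifier", "profile", "label")
  if (!all(required %in% names(dataset))) {
    rlang::abort("dataset needs columns identifier, profile, label")
  }
  if (require_both_classes &&
      length(unique(dataset$label)) < 2) {
    rlang::abort("training requires at least one example of each class")
  }
  invisible(TRUE)
}

#' Read a dataset manifest
#'
#' The manifest is a tab-separated file with a header line and columns
#' `identifier`, `profile_path`, `label`; each profile is loaded with
#' [read_profile()]. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest path.
#' @param format Profile dialect passed to [read_profile()].
#' @return A labeled dataset tibble (see [labeled_dataset()]).
#' @export
read_dataset_manifest <- function(path, format = "normalized_tsv") {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("identifier", "profile_path", "label")
  if (!all(required %in% names(tab))) {
    rlang::abort("manifest needs columns identifier, profile_path, label")
  }
  base <- dirname(path)
  profiles <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$profile_path[i]
    if (!file.exists(p)) p <- file.path(base, tab$profile_path[i])
    prof <- read_profile(p, format = format)
    attr(prof, "identifier") <- tab$identifier[i]
    prof
  })
  labeled_dataset(profiles, tab$label)
}

# window maxima for every profile at every window length; rows follow the
# dataset, columns follow cr_values
window_max_matrix <- function(dataset, cr_values, terminal_exclude) {
  traces <- lapply(dataset$profile, function(p) di_trace(p)$di)
  too_short <- vapply(traces, function(tr) {
    length(tr) - 2L * terminal_exclude < max(cr_values)
  }, logical(1))
  if (any(too_short)) {
    rlang::abort(paste0(
      "profile(s) too short for the largest window after terminal exclusion: ",
      paste(dataset$identifier[too_short], collapse = ", ")))
  }
  vapply(cr_values, function(cr) {
    vapply(traces, max_moving_average, numeric(1),
           cr = cr, terminal_exclude = terminal_exclude)
  }, numeric(nrow(dataset)))
}

confusion_from_wmax <- function(wmax, truth_meta, di_thre) {
  pred_meta <- wmax > di_thre
  tibble::tibble(
    tp = sum(pred_meta & truth_meta),
    fp = sum(pred_meta & !truth_meta),
    tn = sum(!pred_meta & !truth_meta),
    fn = sum(!pred_meta & truth_meta)
  )
}

#' Evaluate a parameter pair on a labeled dataset
#'
#' Classifies every profile with [classify_profile()] at the given window
#' length and threshold and tallies the confusion matrix against the labels,
#' with metamorphic as the positive class.
#'
#' @param dataset A labeled dataset (see [labeled_dataset()]).
#' @param cr Window length in residues.
#' @param di_thre Threshold on the maximum windowed-average diversity index.
#' @param terminal_exclude Residues ignored at each terminus.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_dataset <- function(dataset, cr, di_thre, terminal_exclude = 5) {
  check_dataset(dataset)
  wmax <- window_max_matrix(dataset, cr, terminal_exclude)[, 1]
  confusion_from_wmax(wmax, dataset$label == "metamorphic", di_thre)
}

#' Train the classifier by exhaustive MCC grid search
#'
#' Evaluates every `(cr, di_thre)` combination on the dataset, computing the
#' full confusion matrix, MCC, TPR, TNR and accuracy per cell, and returns
#' the cell with the highest MCC. Ties are broken deterministically by the
#' smallest window length, then the smallest threshold. The defaults cover
#' window lengths 6-15 and thresholds 1.4-2.6 in steps of 0.05 (250 cells).
#'
#' @param dataset A labeled dataset containing both classes.
#' @param cr_values Integer vector of candidate window lengths.
#' @param di_thre_values Numeric vector of candidate thresholds.
#' @param terminal_exclude Residues ignored at each terminus.
#' @return An object of class `di_grid` with elements `table` (the full grid
#'   as a tibble: `cr`, `di_thre`, `tp`, `fp`, `tn`, `fn`, `mcc`, `tpr`,
#'   `tnr`, `acc`), `best_cr`, `best_di_thre`, `best_mcc`,
#'   `terminal_exclude`, `n`. Use [generics::tidy()] for the table,
#'   [generics::glance()] for the optimum, and [ggplot2::autoplot()] for the
#'   MCC heat map.
#' @export
grid_search <- function(dataset,
                        cr_values = 6:15,
                        di_thre_values = seq(1.4, 2.6, by = 0.05),
                        terminal_exclude = 5) {
  check_dataset(dataset, require_both_classes = TRUE)
  stopifnot(length(cr_values) > 0, length(di_thre_values) > 0,
            !is.unsorted(cr_values), !is.unsorted(di_thre_values))
  wmax <- window_max_matrix(dataset, cr_values, terminal_exclude)
  truth <- dataset$label == "metamorphic"
  cells <- tidyr::expand_grid(cr = as.integer(cr_values),
                              di_thre = di_thre_values)
  cms <- purrr::map2(cells$cr, cells$di_thre, function(cr, thr) {
    confusion_from_wmax(wmax[, match(cr, cr_values)], truth, thr)
  })
  tab <- dplyr::bind_cols(cells, dplyr::bind_rows(cms))
  tab$mcc <- mcc(tab)
  tab <- dplyr::bind_cols(tab, rates(tab))
  best <- tab[order(-tab$mcc, tab$cr, tab$di_thre), ][1, ]
  structure(
    list(table = tab,
         best_cr = best$cr,
         best_di_thre = best$di_thre,
         best_mcc = best$mcc,
         terminal_exclude = terminal_exclude,
         n = nrow(dataset)),
    class = "di_grid")
}

#' @export
print.di_grid <- function(x, ...) {
  cat(sprintf(
    "Diversity-index grid search over %d cells (n = %d)\nbest: CR = %d, DI_thre = %.2f, MCC = %.3f\n",
    nrow(x$table), x$n, x$best_cr, x$best_di_thre, x$best_mcc))
  invisible(x)
}

#' @rdname grid_search
#' @param x A `di_grid` object.
#' @param ... Ignored.
#' @method tidy di_grid
#' @export
tidy.di_grid <- function(x, ...) x$table

#' @rdname grid_search
#' @method glance di_grid
#' @export
glance.di_grid <- function(x, ...) {
  best <- x$table[x$table$cr == x$best_cr & x$table$di_thre == x$best_di_thre, ]
  tibble::tibble(cr = x$best_cr, di_thre = x$best_di_thre, mcc = x$best_mcc,
                 tpr = best$tpr, tnr = best$tnr, acc = best$acc, n = x$n)
}

#' Plot the MCC heat map of a grid search
#'
#' @param object A `di_grid` object.
#' @param ... Ignored.
#' @return A ggplot object with the trained optimum marked.
#' @method autoplot di_grid
#' @export
autoplot.di_grid <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$di_thre, y = factor(.data$cr),
                               fill = .data$mcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::annotate("point", x = object$best_di_thre,
                      y = as.character(object$best_cr)) +
    ggplot2::labs(x = "DI threshold", y = "window length (CR)", fill = "MCC") +
    ggplot2::theme_minimal()
}

#' k-fold cross-validation of the grid-searched classifier
#'
#' Shuffles the dataset with the given seed, splits it into `k` chunks whose
#' sizes differ by at most one (the first `n mod k` chunks take the extra
#' entry), and for each fold trains by [grid_search()] on the other `k - 1`
#' chunks and evaluates the selected parameters on the held-out chunk.
#'
#' @inheritParams grid_search
#' @param k Number of folds (default six).
#' @param seed Integer seed controlling the shuffle; identical seeds give
#'   identical fold assignments.
#' @return An object of class `di_cv`: `folds` (per-fold tibble with the
#'   selected parameters, training MCC, and held-out confusion matrix and
#'   metrics) and `summary` (mean and sample SD of the test MCC, TPR, TNR
#'   and accuracy across folds). [generics::tidy()] returns the per-fold
#'   table, [generics::glance()] the summary.
#' @export
cross_validate <- function(dataset, k = 6,
                           cr_values = 6:15,
                           di_thre_values = seq(1.4, 2.6, by = 0.05),
                           terminal_exclude = 5,
                           seed = 1L) {
  check_dataset(dataset, require_both_classes = TRUE)
  n <- nrow(dataset)
  if (k < 2) rlang::abort("k must be at least 2")
  if (k > n) rlang::abort(sprintf("k = %d exceeds dataset size %d", k, n))
  order <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- integer(n)
  fold_of[order] <- rep(seq_len(k), times = sizes)
  folds <- lapply(seq_len(k), function(f) {
    train <- dataset[fold_of != f, ]
    test <- dataset[fold_of == f, ]
    fit <- grid_search(train, cr_values, di_thre_values, terminal_exclude)
    cm <- evaluate_dataset(test, fit$best_cr, fit$best_di_thre, terminal_exclude)
    test_metrics <- if (cm$tp + cm$fn > 0 && cm$tn + cm$fp > 0) {
      rates(cm)
    } else {
      tibble::tibble(tpr = NA_real_, tnr = NA_real_,
                     acc = (cm$tp + cm$tn) / nrow(test))
    }
    dplyr::bind_cols(
      tibble::tibble(fold = f, n_train = nrow(train), n_test = nrow(test),
                     cr = fit$best_cr, di_thre = fit$best_di_thre,
                     train_mcc = fit$best_mcc, test_mcc = mcc(cm)),
      cm, test_metrics)
  })
  folds <- dplyr::bind_rows(folds)
  summ <- tibble::tibble(
    k = k,
    mean_train_mcc = mean(folds$train_mcc),
    sd_train_mcc = stats::sd(folds$train_mcc),
    mean_test_mcc = mean(folds$test_mcc),
    sd_test_mcc = stats::sd(folds$test_mcc),
    mean_tpr = mean(folds$tpr),
    mean_tnr = mean(folds$tnr),
    mean_acc = mean(folds$acc)
  )
  structure(list(folds = folds, summary = summ, seed = seed), class = "di_cv")
}

#' @export
print.di_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validation\nmean test MCC = %.3f (sample SD %.3f); mean train MCC = %.3f\n",
    x$summary$k, x$summary$mean_test_mcc, x$summary$sd_test_mcc,
    x$summary$mean_train_mcc))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `di_cv` object.
#' @param ... Ignored.
#' @method tidy di_cv
#' @export
tidy.di_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @method glance di_cv
#' @export
glance.di_cv <- function(x, ...) x$summary
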