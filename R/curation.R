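#' Windowed secondary-structure mismatch score between two aligned strings
#'
#' Compares two aligned three-state secondary-structure strings column by
#' column: a helix/strand disagreement (`H` vs `E`) costs 2, a coil against
#' either structured state costs 1, identical states and any column with a
#' gap cost 0. The score is the largest cost sum over any `window`
#' consecutive alignment columns; alignments shorter than the window are
#' scored over their full length. A parent structure whose children ever
#' score high against it is suspected of switching folds.
#'
#' @param aligned_ss_a,aligned_ss_b Equal-length strings over `{H, E, C, -}`.
#' @param window Window length in alignment columns (default 30).
#' @return The maximum windowed mismatch score, an integer.
#' @export
#' @examples
#' ss_mismatch_score("HCE", "CCH")  # 1 + 0 + 2 = 3
ss_mismatch_score <- function(aligned_ss_a, aligned_ss_b, window = 30) {
  a <- strsplit(aligned_ss_a, "")[[1]]
  b <- strsplit(aligned_ss_b, "")[[1]]
  if (length(a) != length(b)) {
    rlang::abort(sprintf("aligned strings differ in length (%d vs %d)",
                         length(a), length(b)))
  }
  if (length(a) == 0) return(0L)
  allowed <- c("H", "E", "C", "-")
  bad <- which(!(a %in% allowed) | !(b %in% allowed))
  if (length(bad) > 0) {
    rlang::abort(sprintf("invalid secondary-structure character at column %d ('%s'/'%s')",
                         bad[1], a[bad[1]], b[bad[1]]))
  }
  cost <- integer(length(a))
  gap <- a == "-" | b == "-"
  he <- !gap & ((a == "H" & b == "E") | (a == "E" & b == "H"))
  cx <- !gap & !he & a != b  # coil vs H or E
  cost[he] <- 2L
  cost[cx] <- 1L
  w <- min(window, length(cost))
  cs <- cumsum(c(0L, cost))
  max(cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)])
}

#' Pairwise RMSD after optimal rigid-body superposition
#'
#' Least-squares superposes two matched C-alpha coordinate sets (Kabsch
#' rotation plus translation) and returns the root mean-square deviation in
#' the same units as the input (angstroms for PDB-derived coordinates). The
#' result is zero exactly when the two sets differ by a rigid motion.
#'
#' @param ca_a,ca_b Numeric matrices with one row per aligned residue and
#'   columns x, y, z; at least 3 non-collinear points.
#' @return RMSD after superposition, a non-negative number.
#' @export
pairwise_rmsd <- function(ca_a, ca_b) {
  ca_a <- as.matrix(ca_a); ca_b <- as.matrix(ca_b)
  if (ncol(ca_a) != 3 || ncol(ca_b) != 3) {
    rlang::abort("coordinate sets must have 3 columns (x, y, z)")
  }
  if (nrow(ca_a) != nrow(ca_b)) {
    rlang::abort(sprintf("coordinate sets differ in length (%d vs %d)",
                         nrow(ca_a), nrow(ca_b)))
  }
  if (nrow(ca_a) < 3) rlang::abort("at least 3 aligned points are required")
  if (any(!is.finite(ca_a)) || any(!is.finite(ca_b))) {
    rlang::abort("coordinates must be finite")
  }
  for (m in list(ca_a, ca_b)) {
    sv <- svd(scale(m, scale = FALSE))$d
    if (sv[2] < 1e-8 * max(sv[1], 1)) {
      rlang::abort("degenerate coordinate set (points are collinear)")
    }
  }
  bio3d::rmsd(as.vector(t(ca_a)), as.vector(t(ca_b)), fit = TRUE)
}

#' Metadata screen for likely-monomorphic parent structures
#'
#' Keeps a candidate parent structure only when it is old enough for
#' alternate folds to have surfaced, structurally well determined, richly
#' re-determined (many children), and of globular length: deposited at least
#' `min_age_years` ago, X-ray resolution at most `max_resolution` angstroms
#' (non-X-ray entries, which report no resolution, pass this gate), more
#' than `min_children` deposited structures at >= 50% sequence similarity,
#' and sequence length strictly between `min_len` and `max_len`.
#'
#' @param metadata Data frame with columns `structure_id`,
#'   `deposition_age_years`, `resolution_angstrom` (`NA` for non-X-ray
#'   structures), `n_children_50pct`, `sequence_length`.
#' @param min_age_years,max_resolution,min_children,min_len,max_len
#'   Criterion bounds; see Description.
#' @return The input as a tibble with logical `keep` and, for dropped rows,
#'   `reason` naming the first failed criterion.
#' @export
monomorphic_metadata_filter <- function(metadata,
                                        min_age_years = 10,
                                        max_resolution = 2.2,
                                        min_children = 30,
                                        min_len = 40,
                                        max_len = 250) {
  required <- c("structure_id", "deposition_age_years", "resolution_angstrom",
                "n_children_50pct", "sequence_length")
  if (!all(required %in% names(metadata))) {
    rlang::abort(paste0("metadata needs columns: ", paste(required, collapse = ", ")))
  }
  metadata <- tibble::as_tibble(metadata)
  reason <- rep(NA_character_, nrow(metadata))
  fail <- function(cond, msg) {
    hit <- cond & is.na(reason)
    reason[hit] <<- msg
  }
  fail(metadata$deposition_age_years < min_age_years,
       sprintf("deposited less than %g years ago", min_age_years))
  fail(!is.na(metadata$resolution_angstrom) &
         metadata$resolution_angstrom > max_resolution,
       sprintf("X-ray resolution worse than %g angstroms", max_resolution))
  fail(metadata$n_children_50pct <= min_children,
       sprintf("%d or fewer structures at >=50%% sequence similarity", min_children))
  fail(metadata$sequence_length <= min_len | metadata$sequence_length >= max_len,
       sprintf("sequence length outside (%g, %g)", min_len, max_len))
  metadata$keep <- is.na(reason)
  metadata$reason <- reason
  metadata
}

#' Structural screen of a parent against all of its children
#'
#' Drops a parent structure when any parent-child or child-child pair shows
#' evidence of a fold change: pairwise superposed RMSD exceeding `rmsd_max`
#' angstroms, or a windowed secondary-structure mismatch score exceeding
#' `ss_max`. Both thresholds are strict ("exceeds"), so a pair sitting
#' exactly on a bound is retained.
#'
#' @param pairs A list of structure pairs, each a list with elements
#'   `parent_id`, `child_id`, `aligned_ss_a`, `aligned_ss_b` (equal-length
#'   strings over `{H, E, C, -}`), `ca_a`, `ca_b` (matched coordinate
#'   matrices; see [pairwise_rmsd()]).
#' @param rmsd_max RMSD exclusion threshold in angstroms (default 2.4).
#' @param ss_max Mismatch-score exclusion threshold (default 9).
#' @param ss_window Window length for [ss_mismatch_score()] (default 30).
#' @return A one-row tibble: `keep`, and for drops the `rule`
#'   (`"rmsd"`/`"ss_mismatch"`), offending `parent_id`/`child_id` and the
#'   offending `value`; per-pair `rmsd` and `ss_score` are returned in the
#'   `pairs` list-column.
#' @export
monomorphic_structure_filter <- function(pairs, rmsd_max = 2.4, ss_max = 9,
                                         ss_window = 30) {
  if (length(pairs) == 0) rlang::abort("no structure pairs supplied")
  stats <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(
      parent_id = p$parent_id,
      child_id = p$child_id,
      rmsd = pairwise_rmsd(p$ca_a, p$ca_b),
      ss_score = ss_mismatch_score(p$aligned_ss_a, p$aligned_ss_b, ss_window)
    )
  })
  rmsd_hit <- which(stats$rmsd > rmsd_max)
  ss_hit <- which(stats$ss_score > ss_max)
  if (length(rmsd_hit) > 0) {
    i <- rmsd_hit[1]
    tibble::tibble(keep = FALSE, rule = "rmsd",
                   parent_id = stats$parent_id[i], child_id = stats$child_id[i],
                   value = stats$rmsd[i], pairs = list(stats))
  } else if (length(ss_hit) > 0) {
    i <- ss_hit[1]
    tibble::tibble(keep = FALSE, rule = "ss_mismatch",
                   parent_id = stats$parent_id[i], child_id = stats$child_id[i],
                   value = as.numeric(stats$ss_score[i]), pairs = list(stats))
  } else {
    tibble::tibble(keep = TRUE, rule = NA_character_,
                   parent_id = stats$parent_id[1], child_id = NA_character_,
                   value = NA_real_, pairs = list(stats))
  }
}

#' Keyword screen of publication abstracts for fold-switching language
#'
#' Case-insensitive substring search over a configurable keyword list;
#' structures whose abstracts hint at metamorphic behavior are flagged for
#' exclusion from a monomorphic reference set.
#'
#' @param abstract_text Character vector of abstracts (possibly empty
#'   strings).
#' @param keywords Keyword list; the defaults cover the common ways
#'   fold-switching is announced.
#' @return A tibble with `flagged` and `matched` (comma-separated matched
#'   keywords, `NA` when clean), one row per abstract.
#' @export
keyword_screen <- function(abstract_text,
                           keywords = c("fold switching", "fold-switching",
                                        "fold switch", "metamorphic",
                                        "two folds", "alternate fold",
                                        "dual fold", "conformational switch")) {
  text <- tolower(abstract_text)
  matched <- vapply(text, function(tx) {
    hits <- keywords[vapply(tolower(keywords), grepl, logical(1),
                            x = tx, fixed = TRUE)]
    if (length(hits) == 0) NA_character_ else paste(hits, collapse = ", ")
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(flagged = !is.na(matched), matched = matched)
}

#' Eligibility screen for metamorphic reference candidates
#'
#' The classifier averages the diversity index over a window and ignores
#' residues near the termini, so candidates must be long enough and their
#' fold-switching region (when annotated) must not sit entirely within
#' `terminal_margin` residues of either terminus.
#'
#' @param candidates Data frame with columns `structure_id`,
#'   `sequence_length`, and optional `switch_region_start`,
#'   `switch_region_end` (1-based, `NA` when unannotated).
#' @param min_len Minimum sequence length (default 40).
#' @param terminal_margin Terminal exclusion zone in residues (default 20).
#' @return The input as a tibble with `keep` and a drop `reason`.
#' @export
metamorphic_eligibility <- function(candidates, min_len = 40,
                                    terminal_margin = 20) {
  required <- c("structure_id", "sequence_length")
  if (!all(required %in% names(candidates))) {
    rlang::abort("candidates needs columns structure_id and sequence_length")
  }
  candidates <- tibble::as_tibble(candidates)
  if (!"switch_region_start" %in% names(candidates)) {
    candidates$switch_region_start <- NA_real_
    candidates$switch_region_end <- NA_real_
  }
  st <- candidates$switch_region_start
  en <- candidates$switch_region_end
  len <- candidates$sequence_length
  annotated <- !is.na(st) & !is.na(en)
  if (any(annotated & (st < 1 | st > en | en > len))) {
    rlang::abort("switch region bounds must satisfy 1 <= start <= end <= length")
  }
  reason <- rep(NA_character_, nrow(candidates))
  reason[len < min_len] <- sprintf("sequence shorter than %g residues", min_len)
  terminal <- annotated & is.na(reason) &
    (en <= terminal_margin | st > len - terminal_margin)
  reason[terminal] <- sprintf(
    "fold-switching region within %g residues of a terminus", terminal_margin)
  candidates$keep <- is.na(reason)
  candidates$reason <- reason
  candidates
}

#' Apply audited removals and additions to a reference list count
#'
#' Reference datasets evolve by documented edits: entries withdrawn from the
#' source database, entries failing eligibility, and literature additions.
#' This applies such edits to a base count and returns an audit ledger, so
#' the final tally (e.g. 192 - 8 + 17 = 201 for the metamorphic reference
#' set) is reproducible from the edit lists.
#'
#' @param base_count Size of the starting list.
#' @param removals,additions Data frames with columns `identifier` and
#'   `reason` (either may be empty or `NULL`).
#' @return A list with `final_count` and `ledger`, a tibble with one row per
#'   edit (`action`, `identifier`, `reason`).
#' @export
apply_list_edits <- function(base_count, removals = NULL, additions = NULL) {
  stopifnot(length(base_count) == 1, base_count >= 0)
  as_edits <- function(x, action) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0) {
      return(tibble::tibble(action = character(), identifier = character(),
                            reason = character()))
    }
    x <- tibble::as_tibble(x)
    if (!all(c("identifier", "reason") %in% names(x))) {
      rlang::abort("edit lists need columns identifier and reason")
    }
    tibble::tibble(action = action, identifier = as.character(x$identifier),
                   reason = as.character(x$reason))
  }
  ledger <- dplyr::bind_rows(as_edits(removals, "remove"),
                             as_edits(additions, "add"))
  if (anyDuplicated(ledger$identifier)) {
    dup <- unique(ledger$identifier[duplicated(ledger$identifier)])
    rlang::abort(paste0("duplicate identifier(s) in edits: ",
                        paste(dup, collapse = ", ")))
  }
  list(
    final_count = base_count - sum(ledger$action == "remove") +
      sum(ledger$action == "add"),
    ledger = ledger
  )
}

#' Globally align two amino-acid sequences
#'
#' Convenience wrapper (Needleman-Wunsch via Biostrings, BLOSUM62, gap open
#' -10 / extend -0.5) producing the aligned strings from which curation
#' inputs are built. The structural filters themselves accept pre-aligned
#' inputs, so alignment settings never silently change filter outcomes.
#'
#' @param seq_a,seq_b Amino-acid sequences as single strings.
#' @return A list with `aligned_a` and `aligned_b`, equal-length strings
#'   with `-` gaps.
#' @export
align_sequences <- function(seq_a, seq_b) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("align_sequences requires the Biostrings package")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)))
}
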