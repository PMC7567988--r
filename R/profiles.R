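#' Construct a secondary-structure probability profile
#'
#' An `ss_profile` is a tibble with one row per residue and columns
#' `position` (1-based, contiguous), `residue` (one-letter amino-acid code,
#' `"X"` when unknown), and the three-state probabilities `p_h`, `p_e`,
#' `p_c`. On construction each row is renormalized to sum to exactly 1; rows
#' whose raw sum falls outside `1 +/- tol` are rejected as corrupt. The
#' sequence identifier and originating predictor are carried as attributes.
#'
#' @param x A data frame with columns `position`, `residue`, `p_h`, `p_e`,
#'   `p_c` (extra columns are dropped).
#' @param identifier Free-text sequence identifier.
#' @param source Tag naming the originating secondary-structure predictor,
#'   or `"synthetic"`.
#' @param tol Maximum allowed deviation of a raw row sum from 1 before the
#'   row is treated as corrupt. Predictors print 3-decimal probabilities
#'   that rarely sum exactly to one; the default accepts up to 5% drift.
#'
#' @return A tibble of class `ss_profile` whose probability rows each sum to
#'   1 within 1e-9.
#' @export
#' @examples
#' ss_profile(
#'   data.frame(position = 1:2, residue = c("M", "K"),
#'              p_h = c(0.9, 0.1), p_e = c(0.05, 0.8), p_c = c(0.05, 0.1)),
#'   identifier = "toy"
#' )
ss_profile <- function(x, identifier, source = "synthetic", tol = 0.05) {
  required <- c("position", "residue", "p_h", "p_e", "p_c")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("profile is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[required]
  if (nrow(x) < 1) rlang::abort("profile must contain at least one residue")
  if (!identical(as.integer(x$position), seq_len(nrow(x)))) {
    rlang::abort("positions must be contiguous 1..L with no gaps or duplicates")
  }
  p <- as.matrix(x[c("p_h", "p_e", "p_c")])
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("probabilities must be finite and lie in [0, 1]")
  }
  sums <- rowSums(p)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "row %d: probabilities sum to %.4f, outside [%.2f, %.2f]",
      bad[1], sums[bad[1]], 1 - tol, 1 + tol))
  }
  p <- p / sums
  x$p_h <- unname(p[, 1])
  x$p_e <- unname(p[, 2])
  x$p_c <- unname(p[, 3])
  structure(x,
            identifier = as.character(identifier),
            source_program = as.character(source),
            class = c("ss_profile", class(tibble::tibble())))
}

#' @export
print.ss_profile <- function(x, ...) {
  cat(sprintf("# ss_profile: %s (%d residues, source: %s)\n",
              attr(x, "identifier"), nrow(x), attr(x, "source_program")))
  NextMethod()
}

profile_id <- function(profile) attr(profile, "identifier")

#' Read a secondary-structure probability profile from disk
#'
#' Supports two dialects: PSIPRED `.ss2` output (`format = "psipred_ss2"`;
#' comment and blank lines are skipped, data columns are residue index,
#' residue, predicted state letter, then the coil, helix and strand
#' probabilities — the state letter is ignored) and the package's own
#' normalized tab-separated format (`format = "normalized_tsv"`; a
#' `# id=<identifier> source=<program>` header line followed by
#' `position residue p_h p_e p_c` rows, as written by [write_profile()]).
#'
#' @param path Path to the profile file.
#' @param format One of `"psipred_ss2"`, `"normalized_tsv"`.
#' @param identifier Identifier to attach when the format does not carry one
#'   (ss2 files do not); defaults to the file name without extension.
#'
#' @return An [ss_profile()] with rows renormalized to sum to 1.
#' @export
read_profile <- function(path, format = c("psipred_ss2", "normalized_tsv"),
                         identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "psipred_ss2") {
    parse_ss2(lines, path, identifier)
  } else {
    parse_normalized_tsv(lines, path)
  }
}

parse_ss2 <- function(lines, path, identifier) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) rlang::abort(paste0("no data rows in ", path))
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6) {
      rlang::abort(sprintf("%s: malformed line %d (expected 6 fields, got %d)",
                           path, i, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[4:6]))
    if (any(is.na(num))) {
      rlang::abort(sprintf("%s: malformed line %d (non-numeric probability)",
                           path, i))
    }
    # ss2 column order: coil, helix, strand
    list(position = as.integer(f[1]), residue = f[2],
         p_h = num[2], p_e = num[3], p_c = num[1])
  })
  df <- dplyr::bind_rows(rows)
  if (is.null(identifier)) {
    identifier <- sub("\\.[^.]*$", "", basename(path))
  }
  ss_profile(df, identifier = identifier, source = "psipred")
}

parse_normalized_tsv <- function(lines, path) {
  if (length(lines) == 0) rlang::abort(paste0("empty file: ", path))
  header <- lines[1]
  m_id <- regmatches(header, regexec("id=(\\S+)", header))[[1]]
  m_src <- regmatches(header, regexec("source=(\\S+)", header))[[1]]
  if (!startsWith(header, "#") || length(m_id) < 2) {
    rlang::abort(paste0(path, ": line 1 is not a '# id=... source=...' header"))
  }
  src <- if (length(m_src) >= 2) m_src[2] else "unknown"
  body <- lines[-1]
  body_idx <- which(!grepl("^\\s*$", body)) + 1L
  if (length(body_idx) == 0) rlang::abort(paste0("no data rows in ", path))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5) {
      rlang::abort(sprintf("%s: malformed line %d (expected 5 tab-separated fields, got %d)",
                           path, i, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(1, 3, 4, 5)]))
    if (any(is.na(num))) {
      rlang::abort(sprintf("%s: malformed line %d (non-numeric field)", path, i))
    }
    list(position = as.integer(num[1]), residue = f[2],
         p_h = num[2], p_e = num[3], p_c = num[4])
  })
  ss_profile(dplyr::bind_rows(rows), identifier = m_id[2], source = src)
}

#' Write a profile in the normalized tab-separated format
#'
#' Writes the dialect read back by `read_profile(format = "normalized_tsv")`:
#' a `# id=... source=...` header then one `position residue p_h p_e p_c`
#' row per residue with 6-decimal probabilities, so a write/read round trip
#' preserves probabilities to within 1e-6.
#'
#' @param profile An [ss_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ss_profile"))
  header <- sprintf("# id=%s source=%s",
                    attr(profile, "identifier"), attr(profile, "source_program"))
  body <- sprintf("%d\t%s\t%.6f\t%.6f\t%.6f",
                  profile$position, profile$residue,
                  profile$p_h, profile$p_e, profile$p_c)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Reduce an eight-state DSSP secondary-structure string to three states
#'
#' Applies the standard DSSP reduction: `H`, `G`, `I` (helices) map to `H`;
#' `E`, `B` (strands/bridges) map to `E`; everything else (`T`, `S`, `-`,
#' space, `C`) maps to coil `C`.
#'
#' @param ss8 Character vector of strings over the eight-state DSSP alphabet.
#' @return Character vector of equal-length strings over `{H, E, C}`.
#' @export
#' @examples
#' reduce_dssp_8to3("HGIEBTS- C")
reduce_dssp_8to3 <- function(ss8) {
  vapply(ss8, function(s) {
    if (nchar(s) == 0) return("")
    chars <- strsplit(s, "")[[1]]
    allowed <- c("H", "G", "I", "E", "B", "T", "S", "-", " ", "C")
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0) {
      rlang::abort(sprintf("unknown secondary-structure character '%s' at position %d",
                           chars[bad[1]], bad[1]))
    }
    out <- rep("C", length(chars))
    out[chars %in% c("H", "G", "I")] <- "H"
    out[chars %in% c("E", "B")] <- "E"
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
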