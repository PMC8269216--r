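# Reading, writing and normalizing PSI-BLAST ASCII profiles, plus FASTA I/O.

#' Create a protein record
#'
#' @param id Protein identifier (nonempty string).
#' @param sequence Amino-acid sequence; uppercased on construction. Canonical
#'   residues plus `X`, `B`, `Z`, `U` are accepted unless `strict = TRUE`.
#' @param label Optional class label, `"virion"` or `"nonvirion"`.
#' @param strict Reject noncanonical residues instead of tolerating them.
#'
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   and `label`.
#' @export
protein_record <- function(id, sequence, label = NA_character_, strict = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) {
    stop("protein '", id, "': sequence must have length >= 1", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, AA_NONCANONICAL))
  if (length(bad) > 0L) {
    stop("protein '", id, "': invalid residue letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  noncan <- intersect(unique(chars), AA_NONCANONICAL)
  if (strict && length(noncan) > 0L) {
    stop("protein '", id, "': noncanonical residue(s) ",
         paste(noncan, collapse = ", "), " rejected in strict mode",
         call. = FALSE)
  }
  if (!is.na(label) && !label %in% c("virion", "nonvirion")) {
    stop("label must be 'virion', 'nonvirion' or NA", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, label = label),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa%s)\n", x$id, nchar(x$sequence),
              if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Read a multi-record FASTA file of protein sequences
#'
#' Sequences are uppercased; record order is preserved; the identifier is the
#' header text up to the first whitespace.
#'
#' @param path FASTA file path.
#' @param label Optional label attached to every record.
#' @param strict Reject noncanonical residues.
#'
#' @return List of [protein_record()] objects.
#' @export
read_fasta <- function(path, label = NA_character_, strict = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- as.character(set)
  mapply(function(i, s) protein_record(i, s, label = label, strict = strict),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# ---------------------------------------------------------------------------

.new_pssm_profile <- function(protein_id, raw, sequence,
                              column_order = AA_ALPHABET, norm = NULL) {
  stopifnot(is.matrix(raw), ncol(raw) == 20L)
  storage.mode(raw) <- "double"
  dimnames(raw) <- list(NULL, AA_ALPHABET)
  structure(list(protein_id = protein_id,
                 length = nrow(raw),
                 raw = raw,
                 norm = norm,
                 sequence = sequence,
                 column_order = column_order),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d x 20 (%s)\n", x$protein_id, x$length,
              if (is.null(x$norm)) "raw only" else "normalized"))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: a header line listing the 20 residue
#' columns (once or twice), followed by one row per sequence position holding
#' the position index, the query residue, 20 integer log-odds scores and
#' (optionally) 20 weighted-percentage columns. Columns are re-mapped from the
#' file's header order to the fixed alphabetical order [AA_ALPHABET] so all
#' encoders index residues identically.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file stem.
#'
#' @return A `pssm_profile` with fields `protein_id`, `length`, `raw` (L x 20
#'   integer log-odds), `norm` (`NULL` until [normalize_pssm()]), `sequence`
#'   (the query residues from column 2, for cross-checking) and
#'   `column_order` (the file's header order). The percentage block, when
#'   present, is kept in attribute `"percent"` (also re-mapped).
#' @export
parse_ascii_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)

  header_idx <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(tok) %in% c(20L, 40L) && all(tok %in% AA_ALPHABET)) {
      header_idx <- i
      column_order <- tok[1:20]
      break
    }
  }
  if (is.na(header_idx)) {
    stop("malformed PSSM '", path, "': no 20-residue header line found",
         call. = FALSE)
  }
  if (anyDuplicated(column_order)) {
    stop("malformed PSSM '", path, "': header line ", header_idx,
         " repeats residue columns", call. = FALSE)
  }

  raw_rows <- list(); pct_rows <- list(); residues <- character(0)
  pos <- integer(0)
  i <- header_idx + 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!grepl("^[0-9]+\\s+[A-Z*]", ln)) break
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (length(tok) < 22L) {
      stop("parse error in '", path, "' at line ", i,
           ": expected at least 20 score columns, found ", length(tok) - 2L,
           call. = FALSE)
    }
    scores <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(scores)) {
      stop("parse error in '", path, "' at line ", i,
           ": non-numeric score cell", call. = FALSE)
    }
    pct <- NULL
    if (length(tok) >= 42L) {
      pct <- suppressWarnings(as.numeric(tok[23:42]))
      if (anyNA(pct)) {
        stop("parse error in '", path, "' at line ", i,
             ": non-numeric percentage cell", call. = FALSE)
      }
    }
    pos <- c(pos, as.integer(tok[1L]))
    residues <- c(residues, tok[2L])
    raw_rows[[length(raw_rows) + 1L]] <- scores
    if (!is.null(pct)) pct_rows[[length(pct_rows) + 1L]] <- pct
    i <- i + 1L
  }
  L <- length(raw_rows)
  if (L == 0L) {
    stop("malformed PSSM '", path, "': no data rows after header line ",
         header_idx, call. = FALSE)
  }
  if (!identical(pos, seq_len(L))) {
    stop("integrity error in '", path, "': position indices are not 1..",
         L, call. = FALSE)
  }
  if (length(pct_rows) > 0L && length(pct_rows) != L) {
    stop("integrity error in '", path,
         "': percentage block present for only some rows", call. = FALSE)
  }

  perm <- match(AA_ALPHABET, column_order)
  raw <- do.call(rbind, raw_rows)[, perm, drop = FALSE]
  prof <- .new_pssm_profile(protein_id, raw,
                            sequence = paste(residues, collapse = ""),
                            column_order = column_order)
  if (length(pct_rows) > 0L) {
    pct <- do.call(rbind, pct_rows)[, perm, drop = FALSE]
    dimnames(pct) <- list(NULL, AA_ALPHABET)
    attr(prof, "percent") <- pct
  }
  prof
}

#' Write a profile as a PSI-BLAST style ASCII PSSM
#'
#' Emits the two-block ASCII layout (log-odds then percentages) with columns
#' in the PSI-BLAST header order, so generated fixtures exercise the same
#' re-mapping path as genuine files. Re-parsing reproduces `raw` exactly.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  perm <- match(PSIBLAST_COLUMN_ORDER, AA_ALPHABET)
  raw <- profile$raw[, perm, drop = FALSE]
  pct <- attr(profile, "percent")
  if (is.null(pct)) {
    pct <- round(100 * stats::plogis(profile$raw))
  }
  pct <- pct[, perm, drop = FALSE]
  res <- strsplit(profile$sequence, "", fixed = TRUE)[[1L]]

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               paste("Last position-specific scoring matrix computed,",
                     "weighted observed percentages rounded down,",
                     "information per position, and relative weight of",
                     "gapless real matches to pseudocounts")), con)
  writeLines(paste0("            ",
                    paste(sprintf("%4s", PSIBLAST_COLUMN_ORDER), collapse = ""),
                    "  ",
                    paste(sprintf("%4s", PSIBLAST_COLUMN_ORDER), collapse = "")),
             con)
  for (k in seq_len(profile$length)) {
    writeLines(paste0(sprintf("%5d %s ", k, res[k]),
                      paste(sprintf("%4d", raw[k, ]), collapse = ""),
                      "  ",
                      paste(sprintf("%4d", pct[k, ]), collapse = ""),
                      sprintf("  %5.2f %9.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1375     0.3160",
               "Standard Gapped      0.0410     0.2670"), con)
  invisible(path)
}

#' Normalize a profile's log-odds scores to [0, 1]
#'
#' The default maps each integer log-odds score through the logistic sigmoid
#' `1 / (1 + exp(-x))`, the convention of standard PSSM feature toolkits, so
#' every entry becomes a per-position residue probability in (0, 1).
#' Alternatively the file's weighted-percentage block divided by 100 can be
#' used when it was parsed.
#'
#' @param profile A `pssm_profile`.
#' @param method `"sigmoid"` (default) or `"percent"`.
#' @return The profile with `norm` populated (L x 20, entries in \[0, 1\]).
#' @export
normalize_pssm <- function(profile, method = c("sigmoid", "percent")) {
  stopifnot(inherits(profile, "pssm_profile"))
  method <- match.arg(method)
  if (method == "sigmoid") {
    norm <- stats::plogis(profile$raw)
  } else {
    pct <- attr(profile, "percent")
    if (is.null(pct)) {
      stop("profile '", profile$protein_id,
           "' has no percentage block; cannot use method = 'percent'",
           call. = FALSE)
    }
    norm <- pct / 100
  }
  dimnames(norm) <- list(NULL, AA_ALPHABET)
  profile$norm <- norm
  profile
}

# Validate the structural invariants of a profile; returns TRUE or stops.
.check_profile <- function(profile, sequence = NULL) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (nrow(profile$raw) != profile$length || ncol(profile$raw) != 20L) {
    stop("profile '", profile$protein_id, "': raw must be length x 20",
         call. = FALSE)
  }
  if (!is.null(profile$norm)) {
    if (!all(dim(profile$norm) == c(profile$length, 20L))) {
      stop("profile '", profile$protein_id, "': norm must be length x 20",
           call. = FALSE)
    }
    if (any(profile$norm < 0 | profile$norm > 1)) {
      stop("profile '", profile$protein_id, "': norm entries outside [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.null(sequence) && nchar(sequence) != profile$length) {
    stop("integrity error: profile '", profile$protein_id, "' has ",
         profile$length, " rows but the sequence has ", nchar(sequence),
         " residues", call. = FALSE)
  }
  invisible(TRUE)
}

# Fetch the normalized matrix, normalizing on the fly if needed.
.norm_matrix <- function(profile) {
  if (is.null(profile$norm)) profile <- normalize_pssm(profile)
  profile$norm
}
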