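#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a sequence-record table. The header token up to
#' the first whitespace becomes the protein identifier; multi-line sequences
#' are joined and residues upper-cased. Non-standard residue letters
#' (B, J, O, U, X, Z) are accepted with a warning; how they encode is decided
#' at encoding time (see [encode_sequence()]).
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `protein_id` and `residues`, one row per
#'   FASTA entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) {
    stop("FASTA file contains no sequences: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate protein identifier(s) in FASTA: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  residues <- toupper(as.character(seqs))
  if (any(!nzchar(residues))) {
    stop("empty sequence for identifier(s): ",
         paste(ids[!nzchar(residues)], collapse = ", "), call. = FALSE)
  }
  ns <- vapply(residues, function(s) {
    any(strsplit(s, "")[[1]] %in% .nonstandard_aa)
  }, logical(1))
  if (any(ns)) {
    warning("non-standard residue letters in: ",
            paste(ids[ns], collapse = ", "), call. = FALSE)
  }
  data.frame(protein_id = ids, residues = unname(residues),
             stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records Data.frame with columns `protein_id`, `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$residues)
  names(x) <- records$protein_id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a labeled interaction-pair list
#'
#' Reads a 3-column delimited text file (`id_a id_b label`), tab- or
#' whitespace-separated, one pair per line; `#` starts a comment. Labels must
#' be 0 (non-interacting) or 1 (interacting). Pairs are unordered: `(a,b)` and
#' `(b,a)` are the same pair, so the same unordered pair appearing with both
#' labels is an integrity error; exact duplicates are collapsed to one pair.
#'
#' @param path Path to the pair list.
#' @param records Sequence records (from [read_fasta()]); every identifier in
#'   the file must resolve to a record.
#' @param allow_self Permit self-interactions (`id_a == id_b`)? Default FALSE.
#' @return A data.frame with columns `id_a`, `id_b`, `label` (integer 0/1).
#' @export
read_pairs <- function(path, records, allow_self = FALSE) {
  if (!file.exists(path)) {
    stop("pair file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("pair file contains no pairs: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop("malformed pair line(s) (expected 3 columns): line ",
         paste(which(nf != 3L), collapse = ", "), call. = FALSE)
  }
  id_a <- vapply(fields, `[[`, character(1), 1L)
  id_b <- vapply(fields, `[[`, character(1), 2L)
  lab_chr <- vapply(fields, `[[`, character(1), 3L)
  if (!all(lab_chr %in% c("0", "1"))) {
    stop("label outside {0,1} at line ",
         paste(which(!lab_chr %in% c("0", "1")), collapse = ", "),
         call. = FALSE)
  }
  label <- as.integer(lab_chr)
  unknown <- setdiff(unique(c(id_a, id_b)), records$protein_id)
  if (length(unknown) > 0) {
    stop("pair list references unknown identifier(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!allow_self && any(id_a == id_b)) {
    stop("self-interaction(s) not permitted: ",
         paste(unique(id_a[id_a == id_b]), collapse = ", "), call. = FALSE)
  }
  key <- pair_key(id_a, id_b)
  conflicting <- unique(key[duplicated(key) | duplicated(key, fromLast = TRUE)])
  for (k in conflicting) {
    if (length(unique(label[key == k])) > 1L) {
      stop("conflicting labels for unordered pair ", k, call. = FALSE)
    }
  }
  keep <- !duplicated(key)
  data.frame(id_a = id_a[keep], id_b = id_b[keep], label = label[keep],
             stringsAsFactors = FALSE)
}

# canonical key of an unordered pair
pair_key <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "\r")
}

#' Write an interaction-pair list
#'
#' Tab-delimited, three columns, no header; the format read by
#' [read_pairs()]. Writing then re-reading reproduces the pair set.
#'
#' @param pairs Data.frame with columns `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_a", "id_b", "label")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a PPI dataset from records and pairs
#'
#' Bundles sequence records and labeled pairs into a validated dataset
#' object. Every identifier referenced by `pairs` must exist in `records`;
#' identifiers must be unique and non-empty; no unordered pair may carry
#' conflicting labels.
#'
#' @param records Data.frame with `protein_id`, `residues`.
#' @param pairs Data.frame with `id_a`, `id_b`, `label`.
#' @param name Dataset name (default "dataset").
#' @return An object of class `ppi_dataset`: a list with elements `records`,
#'   `pairs`, `name`.
#' @export
ppi_dataset <- function(records, pairs, name = "dataset") {
  stopifnot(is.data.frame(records), is.data.frame(pairs))
  records <- as.data.frame(records)[, c("protein_id", "residues")]
  pairs <- as.data.frame(pairs)[, c("id_a", "id_b", "label")]
  if (any(!nzchar(records$protein_id))) {
    stop("empty protein identifier in records", call. = FALSE)
  }
  dup <- unique(records$protein_id[duplicated(records$protein_id)])
  if (length(dup) > 0) {
    stop("duplicate protein identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(records$residues) < 1L)) {
    stop("zero-length residue string in records", call. = FALSE)
  }
  unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), records$protein_id)
  if (length(unknown) > 0) {
    stop("pairs reference unknown identifier(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(pairs$label %in% c(0L, 1L))) {
    stop("pair labels must be 0 or 1", call. = FALSE)
  }
  key <- pair_key(pairs$id_a, pairs$id_b)
  agg <- tapply(pairs$label, key, function(x) length(unique(x)))
  if (any(agg > 1L)) {
    stop("conflicting labels for unordered pair(s): ",
         paste(gsub("\r", "--", names(agg)[agg > 1L]), collapse = ", "),
         call. = FALSE)
  }
  pairs$label <- as.integer(pairs$label)
  structure(list(records = records, pairs = pairs, name = name),
            class = "ppi_dataset")
}

#' @export
print.ppi_dataset <- function(x, ...) {
  cat("ppi_dataset:", x$name, "\n")
  cat("  proteins:", nrow(x$records), "\n")
  cat("  pairs:", nrow(x$pairs),
      sprintf("(%d positive, %d negative)\n",
              sum(x$pairs$label == 1L), sum(x$pairs$label == 0L)))
  invisible(x)
}

#' Benchmark profile for the S. cerevisiae core set
#'
#' The published composition of the S. cerevisiae core benchmark: 11188
#' labeled pairs, 5594 positive and 5594 negative, with every protein at
#' least 50 residues long (shorter proteins were removed upstream, as was
#' redundancy above 40% sequence identity — neither step is re-run here).
#'
#' @return A `benchmark_profile` list with `total`, `positives`, `negatives`,
#'   `min_residue_length`.
#' @export
scerevisiae_core_profile <- function() {
  benchmark_profile(total = 11188L, positives = 5594L, negatives = 5594L,
                    min_residue_length = 50L,
                    name = "S. cerevisiae core")
}

#' Construct a benchmark profile
#'
#' @param total Expected total pair count.
#' @param positives Expected positive-pair count.
#' @param negatives Expected negative-pair count.
#' @param min_residue_length Minimum residue length every protein must meet
#'   (NULL to skip the check).
#' @param name Profile name.
#' @return A `benchmark_profile` list.
#' @export
benchmark_profile <- function(total, positives, negatives,
                              min_residue_length = NULL, name = "profile") {
  structure(list(total = as.integer(total), positives = as.integer(positives),
                 negatives = as.integer(negatives),
                 min_residue_length = min_residue_length, name = name),
            class = "benchmark_profile")
}

#' Verify a dataset against a benchmark profile
#'
#' Compares a loaded dataset's pair counts and minimum residue length with a
#' stated profile. Failures are reported, never raised, so a report is always
#' produced. The observed total always equals positives + negatives.
#'
#' @param dataset A [ppi_dataset()].
#' @param expected A [benchmark_profile()].
#' @return A `benchmark_report`: data.frame with columns `check`, `expected`,
#'   `observed`, `pass`, printed as `key: value` lines.
#' @export
verify_benchmark <- function(dataset, expected) {
  stopifnot(inherits(dataset, "ppi_dataset"),
            inherits(expected, "benchmark_profile"))
  npos <- sum(dataset$pairs$label == 1L)
  nneg <- sum(dataset$pairs$label == 0L)
  ntot <- nrow(dataset$pairs)
  minlen <- min(nchar(dataset$records$residues))
  checks <- data.frame(
    check = c("total_pairs", "positive_pairs", "negative_pairs"),
    expected = c(expected$total, expected$positives, expected$negatives),
    observed = c(ntot, npos, nneg),
    stringsAsFactors = FALSE
  )
  if (!is.null(expected$min_residue_length)) {
    checks <- rbind(checks, data.frame(
      check = "min_residue_length_at_least",
      expected = as.integer(expected$min_residue_length),
      observed = minlen))
  }
  checks$pass <- ifelse(checks$check == "min_residue_length_at_least",
                        checks$observed >= checks$expected,
                        checks$observed == checks$expected)
  structure(checks, class = c("benchmark_report", "data.frame"),
            dataset = dataset$name, profile = expected$name)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark verification:", attr(x, "dataset"), "vs",
      attr(x, "profile"), "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: expected %s, observed %s [%s]\n",
                x$check[i], x$expected[i], x$observed[i],
                if (x$pass[i]) "pass" else "FAIL"))
  }
  cat("overall:", if (all(x$pass)) "pass" else "FAIL", "\n")
  invisible(x)
}
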