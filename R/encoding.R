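#' The 20-letter amino-acid alphabet used for one-hot encoding
#'
#' Returns the ordered vector of the 20 standard amino-acid one-letter codes.
#' The order is alphabetical (A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S,
#' T, V, W, Y) and is frozen: channel `i` of every one-hot matrix always
#' corresponds to `aa_alphabet()[i]`.
#'
#' Non-standard letters (B, J, O, U, X, Z) are not part of the alphabet; they
#' encode as an all-zero row (see [encode_sequence()]).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# letters accepted on read but encoded as zero rows
.nonstandard_aa <- c("B", "J", "O", "U", "X", "Z")

#' One-hot encode an amino-acid sequence at a fixed length
#'
#' Converts a protein sequence into an `L x 20` binary matrix. Each standard
#' residue becomes a unit row at its alphabet index. Sequences shorter than
#' `L` are padded with all-zero rows at the FRONT (the last `nchar` rows carry
#' the residues, in order); sequences longer than `L` are truncated at the
#' FRONT (only the last `L` residues are encoded). Non-standard residue
#' letters (B, J, O, U, X, Z) encode as all-zero rows with a warning.
#'
#' @param residues A single sequence string, or a list/data.frame record with
#'   elements `protein_id` and `residues`.
#' @param L Fixed encoding length (rows of the output); default 850, the
#'   conventional cap on protein length for this representation.
#' @return An `L x 20` 0/1 matrix of class `onehot_matrix`, with attributes
#'   `source_length` (original residue count) and `L`. Columns are named by
#'   [aa_alphabet()].
#' @export
#' @examples
#' m <- encode_sequence("MKV", L = 6)
#' colSums(m)   # one M, one K, one V
#' rowSums(m)   # three leading padding rows, then three unit rows
encode_sequence <- function(residues, L = 850) {
  if (is.list(residues) && !is.null(residues$residues)) {
    residues <- residues$residues
  }
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1) {
    stop("`L` must be a positive integer", call. = FALSE)
  }
  L <- as.integer(L)
  if (!nzchar(residues)) {
    stop("cannot encode an empty residue string", call. = FALSE)
  }
  chars <- strsplit(toupper(residues), "")[[1]]
  src_len <- length(chars)
  bad <- setdiff(unique(chars), c(aa_alphabet(), .nonstandard_aa))
  if (length(bad) > 0) {
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(chars %in% .nonstandard_aa)) {
    warning("non-standard residue letter(s) ",
            paste(intersect(unique(chars), .nonstandard_aa), collapse = ", "),
            " encoded as all-zero rows", call. = FALSE)
  }
  if (src_len > L) {
    chars <- chars[(src_len - L + 1L):src_len]  # keep the LAST L residues
  }
  idx <- match(chars, aa_alphabet())            # NA for non-standard
  m <- matrix(0L, nrow = L, ncol = 20L,
              dimnames = list(NULL, aa_alphabet()))
  rows <- (L - length(chars) + 1L):L            # front padding
  keep <- !is.na(idx)
  m[cbind(rows[keep], idx[keep])] <- 1L
  structure(m, source_length = src_len, L = L, class = c("onehot_matrix", "matrix"))
}

#' Flatten a one-hot matrix into a sequence feature vector
#'
#' Row-major flattening: the 20 channels of residue position 1 come first,
#' then position 2, and so on. The result has length `L * 20` and sums to the
#' number of encoded residues, `min(source_length, L)`.
#'
#' @param matrix An `L x 20` matrix from [encode_sequence()].
#' @return Numeric vector of length `L * 20`.
#' @export
flatten_encoding <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 20L)
  as.numeric(t(matrix))
}

# Flattened encodings for a set of records: one row per protein, L*20 columns.
# Warnings about non-standard residues are raised once per offending protein.
sequence_feature_matrix <- function(records, L) {
  S <- matrix(0, nrow = nrow(records), ncol = L * 20L)
  rownames(S) <- records$protein_id
  for (i in seq_len(nrow(records))) {
    S[i, ] <- flatten_encoding(encode_sequence(records$residues[[i]], L = L))
  }
  S
}
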