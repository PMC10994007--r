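#' Normalize an MHC class-I allele name
#'
#' Brings allele spellings into the canonical `"HLA-A*02:01"` form:
#' whitespace is stripped, letters are upper-cased, and the `"HLA-"`
#' prefix, `"*"` and `":"` separators are inserted when the digits permit
#' unambiguous parsing. Ambiguous strings are an error, never guessed.
#' Names in the synthetic namespace (prefix `"SYN-"`) are passed through
#' unchanged apart from case/whitespace cleanup, so synthetic alleles can
#' flow through the same pipelines as real ones.
#'
#' @param raw character vector of allele spellings.
#' @return character vector of normalized names, same length as `raw`.
#'   Normalization is idempotent.
#' @examples
#' normalize_allele(c("HLA-A*02:01", "HLA-A0201", "B0801", "a*02:01"))
#' @export
normalize_allele <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L) {
    stop("'raw' must be a non-empty character vector")
  }
  x <- toupper(gsub("[[:space:]]+", "", raw))
  if (any(!nzchar(x))) {
    stop("empty allele name at position ", which(!nzchar(x))[1L])
  }
  out <- character(length(x))
  syn <- startsWith(x, "SYN-")
  out[syn] <- x[syn]
  todo <- which(!syn)
  for (i in todo) {
    s <- sub("^HLA-?", "", x[i])
    # separator-carrying forms first; bare digits only split unambiguously
    # as 2+2, so exactly four of them are accepted
    pats <- c("^([A-Z])\\*([0-9]{1,3}):([0-9]{1,3})$",
              "^([A-Z])([0-9]{2}):([0-9]{2,3})$",
              "^([A-Z])\\*([0-9]{2})([0-9]{2})$",
              "^([A-Z])([0-9]{2})([0-9]{2})$")
    m <- character(0)
    for (p in pats) {
      m <- regmatches(s, regexec(p, s))[[1L]]
      if (length(m) == 4L) break
    }
    if (length(m) != 4L) {
      stop("cannot parse allele name: '", raw[i], "'")
    }
    out[i] <- sprintf("HLA-%s*%02d:%02d",
                      m[2L], as.integer(m[3L]), as.integer(m[4L]))
  }
  out
}

#' Load an allele-to-pseudo-sequence mapping table
#'
#' Reads a two-column tab-delimited file (allele name, pseudo-sequence).
#' Allele names are normalized with [normalize_allele()]; all
#' pseudo-sequences must share one length P (the fixed set of MHC groove
#' contact residues used as the pan-allele representation).
#'
#' The table bundled with the package
#' (`system.file("extdata", "pseudosequences_synthetic.tsv", package =
#' "tlmhc")`) carries *synthetic placeholder* pseudo-sequences of length 34
#' for a panel of common allele names; supply a curated table for real
#' analyses.
#'
#' @param path path to the TSV file, or `NULL` for the bundled synthetic
#'   table.
#' @return named character vector: normalized allele name -> pseudo-sequence.
#' @export
load_pseudosequence_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pseudosequences_synthetic.tsv",
                        package = "tlmhc", mustWork = TRUE)
  }
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(tab) < 2L) stop("pseudo-sequence table needs two columns")
  ps <- toupper(tab[[2L]])
  if (length(unique(nchar(ps))) != 1L) {
    stop("pseudo-sequences must all share one length, found lengths: ",
         paste(unique(nchar(ps)), collapse = ", "))
  }
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), ps)
  if (any(bad)) stop("non-canonical residue in pseudo-sequence for ", tab[[1L]][bad][1L])
  setNames(ps, normalize_allele(tab[[1L]]))
}

#' Look up the pseudo-sequence for an allele
#'
#' @param name allele name (any spelling; normalized internally).
#' @param table named vector from [load_pseudosequence_table()].
#' @return pseudo-sequence string.
#' @export
allele_to_pseudosequence <- function(name, table) {
  key <- normalize_allele(name)
  hit <- table[key]
  if (anyNA(hit)) {
    missing <- unique(key[is.na(hit)])
    near <- utils::head(names(table)[order(utils::adist(missing[1L], names(table)))], 3L)
    stop("unsupported allele: ", paste(missing, collapse = ", "),
         "; nearest supported: ", paste(near, collapse = ", "))
  }
  unname(hit)
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})

#' Construct a residue encoding scheme
#'
#' Two schemes are provided: `"blosum62"` (each residue encoded as its
#' BLOSUM62 substitution row divided by 10, the convention of pan-allele
#' binding predictors) and `"one-hot"`. The unknown residue `X` maps to
#' the column-wise mean of the matrix rows; padding positions carry a
#' dedicated all-zero pad vector.
#'
#' @param name `"blosum62"` or `"one-hot"`.
#' @return object of class `tl_encoding_scheme` with elements `name`,
#'   `matrix` (21 rows: 20 residues + `X`; 20 descriptor columns),
#'   `divisor`, `pad_vector`.
#' @export
encoding_scheme <- function(name = c("blosum62", "one-hot")) {
  name <- match.arg(name)
  if (name == "blosum62") {
    m <- blosum62_matrix()
    divisor <- 10
  } else {
    m <- diag(20)
    dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
    divisor <- 1
  }
  m <- rbind(m, colMeans(m))
  rownames(m)[21L] <- AA_UNKNOWN
  structure(
    list(name = name, matrix = m, divisor = divisor,
         pad_vector = rep(0, ncol(m))),
    class = "tl_encoding_scheme"
  )
}

# Split a peptide of length L into the slot indices it occupies within
# max_len positions: the first ceiling(L/2) residues keep the leading
# slots and the remainder keep the trailing slots, so the P2 anchor and
# the C-terminus sit in stable columns while padding fills the middle.
peptide_slots <- function(len, max_len) {
  if (len > max_len) stop("peptide length ", len, " exceeds max_len ", max_len)
  n_head <- ceiling(len / 2)
  n_tail <- len - n_head
  c(seq_len(n_head), if (n_tail > 0) (max_len - n_tail + 1L):max_len)
}

check_peptides <- function(seqs) {
  seqs <- toupper(seqs)
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), AA_UNKNOWN, "]+$"), seqs)
  if (!all(ok)) {
    stop("non-alphabet character in peptide: '", seqs[!ok][1L], "'")
  }
  seqs
}

#' Encode one peptide as a fixed-width numeric block
#'
#' @param peptide peptide string (8-14 residues by default convention).
#' @param scheme a [encoding_scheme()] object.
#' @param max_len number of peptide positions in the block (default 14).
#' @return numeric matrix of `max_len` rows by 20 descriptor columns.
#'   Residue rows are the scheme rows scaled by `1/divisor`; padding rows
#'   (middle positions for peptides shorter than `max_len`) equal the
#'   scheme's pad vector.
#' @export
encode_peptide <- function(peptide, scheme, max_len = 14L) {
  stopifnot(inherits(scheme, "tl_encoding_scheme"), length(peptide) == 1L)
  seq <- check_peptides(peptide)
  len <- nchar(seq)
  if (len < 1L) stop("empty peptide")
  block <- matrix(rep(scheme$pad_vector, each = max_len), nrow = max_len)
  aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(aa, rownames(scheme$matrix))
  block[peptide_slots(len, max_len), ] <- scheme$matrix[idx, , drop = FALSE] / scheme$divisor
  block
}

#' Build the full encoded example for one peptide-allele pair
#'
#' Concatenates the peptide block and the allele pseudo-sequence block.
#'
#' @param peptide peptide string.
#' @param pseudo_sequence pseudo-sequence string (fixed length P).
#' @param scheme a [encoding_scheme()] object.
#' @param max_len peptide positions (default 14).
#' @return list with `peptide_block` (`max_len` x 20), `allele_block`
#'   (P x 20), and `flattened_width` = `(max_len + P) * 20`.
#' @export
build_example <- function(peptide, pseudo_sequence, scheme, max_len = 14L) {
  pb <- encode_peptide(peptide, scheme, max_len)
  ps <- check_peptides(pseudo_sequence)
  aa <- strsplit(ps, "", fixed = TRUE)[[1L]]
  ab <- scheme$matrix[match(aa, rownames(scheme$matrix)), , drop = FALSE] / scheme$divisor
  rownames(ab) <- NULL
  list(peptide_block = pb, allele_block = ab,
       flattened_width = (max_len + nchar(ps)) * ncol(scheme$matrix))
}

#' Encode a whole dataset of peptide-allele pairs as one design matrix
#'
#' Vectorized encoder used by the training and prediction pipelines: each
#' row is the flattened concatenation of a peptide block ([encode_peptide()])
#' and the allele pseudo-sequence block.
#'
#' @param peptides character vector of peptide sequences.
#' @param pseudo_sequences character vector (recycled if length 1) of
#'   pseudo-sequences, one per peptide.
#' @param scheme a [encoding_scheme()] object.
#' @param max_len peptide positions (default 14).
#' @return numeric matrix, `length(peptides)` rows by
#'   `(max_len + P) * 20` columns.
#' @export
encode_dataset <- function(peptides, pseudo_sequences, scheme, max_len = 14L) {
  stopifnot(inherits(scheme, "tl_encoding_scheme"))
  peptides <- check_peptides(peptides)
  if (length(pseudo_sequences) == 1L) {
    pseudo_sequences <- rep(pseudo_sequences, length(peptides))
  }
  stopifnot(length(pseudo_sequences) == length(peptides))
  pseudo_sequences <- check_peptides(pseudo_sequences)
  P <- unique(nchar(pseudo_sequences))
  if (length(P) != 1L) stop("pseudo-sequences must share one length")
  n <- length(peptides)
  d <- ncol(scheme$matrix)
  rows <- scheme$matrix / scheme$divisor
  X <- matrix(rep(scheme$pad_vector, each = n), nrow = n,
              ncol = (max_len + P) * d)
  fill <- function(seqs, rows_sel, slot, col_offset) {
    aa <- substring(seqs, slot, slot)
    idx <- match(aa, rownames(rows))
    cols <- col_offset + seq_len(d)
    X[rows_sel, cols] <<- rows[idx, , drop = FALSE]
  }
  # peptides grouped by length so slot layout is computed once per length
  lens <- nchar(peptides)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    slots <- peptide_slots(L, max_len)
    for (j in seq_len(L)) {
      fill(peptides[sel], sel, j, (slots[j] - 1L) * d)
    }
  }
  for (j in seq_len(P)) {
    fill(pseudo_sequences, seq_len(n), j, (max_len + j - 1L) * d)
  }
  X
}

#' Decode a one-hot peptide block back to its sequence
#'
#' Inverse of [encode_peptide()] for the one-hot scheme; used to verify
#' the encoding round trip. Padding rows decode to nothing.
#'
#' @param block matrix from [encode_peptide()] with a one-hot scheme.
#' @param scheme the one-hot [encoding_scheme()].
#' @return the peptide string.
#' @export
decode_peptide <- function(block, scheme) {
  stopifnot(scheme$name == "one-hot")
  used <- rowSums(abs(block)) > 0
  idx <- apply(block[used, , drop = FALSE], 1L, which.max)
  paste(AA_ALPHABET[idx], collapse = "")
}
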