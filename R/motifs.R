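#' Fragment protein sequences into k-mers
#'
#' Slides a window of width `k` (step 1) over every sequence, skipping
#' windows that contain non-canonical residues. Optionally deduplicates
#' and/or caps the output with seeded uniform subsampling, e.g. to draw
#' 500,000 distinct 9-mers from a proteome for motif analysis.
#'
#' @param proteins named character vector, `AAStringSet`, or FASTA path.
#' @param k window width (e.g. 9).
#' @param dedup drop duplicate peptides (default `TRUE`).
#' @param max_n optional cap; when exceeded, `max_n` windows are drawn
#'   uniformly without replacement.
#' @param seed seed for the subsampling draw.
#' @return character vector of k-mers.
#' @export
fragment_proteome <- function(proteins, k, dedup = TRUE, max_n = NULL,
                              seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  seqs <- toupper(as_protein_vector(proteins))
  lens <- nchar(seqs)
  usable <- lens >= k
  if (!any(usable)) {
    warning("every sequence is shorter than k = ", k)
    return(character(0))
  }
  out <- unlist(lapply(seqs[usable], function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }), use.names = FALSE)
  canon <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), out)
  out <- out[canon]
  if (dedup) out <- unique(out)
  if (!is.null(max_n) && length(out) > max_n) {
    rng <- local_rng(seed)
    out <- out[sort(sample.int(length(out), max_n))]
    rng()
  }
  out
}

#' Select the top-scoring fraction of peptides
#'
#' Keeps exactly `max(1, floor(n * fraction))` peptides with the
#' highest scores, so the top 0.1% of 500,000 peptides is exactly 500.
#' Boundary ties break by stable input order.
#'
#' @param peptides character vector.
#' @param scores one score per peptide.
#' @param fraction fraction to keep, in (0, 1\].
#' @return character vector of selected peptides (score order).
#' @export
select_top_fraction <- function(peptides, scores, fraction) {
  if (length(peptides) == 0L) stop("empty peptide set")
  stopifnot(length(scores) == length(peptides), fraction > 0, fraction <= 1)
  m <- max(1L, floor(length(peptides) * fraction))
  o <- order(scores, decreasing = TRUE, method = "radix")
  peptides[o[seq_len(m)]]
}

#' Build a position frequency matrix
#'
#' Per-position residue frequencies of an equal-length peptide set —
#' the data behind a sequence logo:
#' `f[j, a] = (count[j, a] + pseudocount) / (support + 20 * pseudocount)`.
#'
#' @param peptides character vector, all the same length.
#' @param pseudocount added to every count (default 0 for fidelity to
#'   the raw selection).
#' @return object of class `tl_pfm`: list with `k`, `frequencies`
#'   (`k` x 20, rows sum to 1), `support`, `pseudocount`.
#' @export
build_pfm <- function(peptides, pseudocount = 0) {
  if (length(peptides) == 0L) stop("empty peptide set")
  peptides <- check_peptides(peptides)
  k <- unique(nchar(peptides))
  if (length(k) != 1L) {
    stop("mixed peptide lengths: ", paste(k, collapse = ", "))
  }
  n <- length(peptides)
  freq <- matrix(0, k, 20L, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(k)) {
    counts <- table(factor(substring(peptides, j, j), levels = AA_ALPHABET))
    freq[j, ] <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
  }
  structure(list(k = k, frequencies = freq, support = n,
                 pseudocount = pseudocount),
            class = "tl_pfm")
}

#' Per-position information content of a PFM
#'
#' `IC_j = sum_a f[j,a] * log2(f[j,a] / background_a)` with the
#' convention `0 * log(0) = 0`; under a uniform background this equals
#' `log2(20) - entropy`, the logo-height convention (bits).
#'
#' @param pfm a [build_pfm()] result.
#' @param background length-20 background distribution (default
#'   uniform), summing to 1.
#' @return numeric vector of `k` per-position values in bits.
#' @export
information_content <- function(pfm, background = rep(1 / 20, 20L)) {
  stopifnot(inherits(pfm, "tl_pfm"), length(background) == 20L)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  f <- pfm$frequencies
  if (any(background == 0 & colSums(f) > 0)) {
    stop("zero background frequency for a residue with non-zero PFM frequency")
  }
  apply(f, 1L, function(row) {
    nz <- row > 0
    sum(row[nz] * log2(row[nz] / background[nz]))
  })
}

#' Export a PFM and its information content as TSV
#'
#' Writes `<path>` with columns `position` then the 20 residue
#' frequencies, and `<path_ic>` (when given) with `position`, `bits`.
#'
#' @param pfm a `tl_pfm`.
#' @param path output TSV path for the frequencies.
#' @param path_ic optional output TSV path for information content.
#' @param background background for the IC export.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path, path_ic = NULL,
                      background = rep(1 / 20, 20L)) {
  df <- data.frame(position = seq_len(pfm$k), pfm$frequencies,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_ic)) {
    ic <- data.frame(position = seq_len(pfm$k),
                     bits = information_content(pfm, background))
    write.table(ic, path_ic, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
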