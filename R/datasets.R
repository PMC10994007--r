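#' pMHC record tables
#'
#' The package represents peptide-MHC datasets as plain data frames with
#' one row per (peptide, allele) pair and one of four tasks:
#' * `BA` — binding affinity, labelled in nM (`affinity_nm`, lower =
#'   stronger; 500 nM is the conventional strong-binder cutoff);
#' * `EL` — eluted ligand, a binary mass-spectrometry presented/decoy
#'   flag (`el_label`);
#' * `STAB` — pMHC kinetic stability, a dissociation half-life in hours
#'   (`half_life_hours`);
#' * `IMM` — immunogenicity, binary or continuous strength in \[0,1\]
#'   (`imm_label`), optionally with a donor `recognition_frequency`.
#'
#' Only the columns of the declared task are populated; the others are
#' `NA`. `source` records provenance (for EL hits, the source protein
#' id used for decoy generation) and `is_random_negative` flags
#' stability rows appended by [add_random_negatives()].
#'
#' @param peptide,allele character vectors (alleles are normalized).
#' @param task one of `"BA"`, `"EL"`, `"STAB"`, `"IMM"`.
#' @param affinity_nm,half_life_hours,imm_label,recognition_frequency
#'   numeric task labels.
#' @param el_label character, `"hit"` or `"decoy"`.
#' @param source character provenance tag.
#' @param is_random_negative logical.
#' @return data frame of class `tl_records`.
#' @export
pmhc_records <- function(peptide, allele, task,
                         affinity_nm = NA_real_, el_label = NA_character_,
                         half_life_hours = NA_real_, imm_label = NA_real_,
                         recognition_frequency = NA_real_,
                         source = NA_character_, is_random_negative = FALSE) {
  task <- match.arg(task, TASKS)
  peptide <- check_peptides(peptide)
  df <- data.frame(
    peptide = peptide,
    allele = normalize_allele(allele),
    task = task,
    affinity_nm = as.numeric(affinity_nm),
    el_label = as.character(el_label),
    half_life_hours = as.numeric(half_life_hours),
    imm_label = as.numeric(imm_label),
    recognition_frequency = as.numeric(recognition_frequency),
    source = as.character(source),
    is_random_negative = as.logical(is_random_negative),
    stringsAsFactors = FALSE
  )
  validate_records(df)
  class(df) <- c("tl_records", "data.frame")
  df
}

RECORD_COLUMNS <- c("peptide", "allele", "task", "affinity_nm", "el_label",
                    "half_life_hours", "imm_label", "recognition_frequency",
                    "source", "is_random_negative")

task_column <- function(task) {
  switch(task, BA = "affinity_nm", EL = "el_label",
         STAB = "half_life_hours", IMM = "imm_label")
}

validate_records <- function(df) {
  stopifnot(all(RECORD_COLUMNS %in% names(df)))
  for (tk in unique(df$task)) {
    sub <- df[df$task == tk, ]
    lab <- sub[[task_column(tk)]]
    if (anyNA(lab)) stop("missing ", task_column(tk), " label in ", tk, " records")
    if (tk == "BA" && any(lab <= 0)) stop("affinity_nm must be > 0")
    if (tk == "STAB" && any(lab < 0)) stop("half_life_hours must be >= 0")
    if (tk == "IMM" && any(lab < 0 | lab > 1)) stop("imm_label must lie in [0, 1]")
    if (tk == "EL" && !all(lab %in% c("hit", "decoy"))) {
      stop("el_label must be 'hit' or 'decoy'")
    }
  }
  invisible(df)
}

#' Read / write pMHC record tables
#'
#' Tab-delimited UTF-8 text with a header holding the full record schema
#' (see [pmhc_records()]); task-irrelevant columns may be empty. Reading
#' validates the task's required column and reports malformed numeric
#' fields with their line numbers. `write_records()` then `read_records()`
#' is the identity on field values.
#'
#' @param path file path.
#' @param task task the file holds (`"BA"`, `"EL"`, `"STAB"`, `"IMM"`);
#'   rows of other tasks are rejected.
#' @param records a `tl_records` data frame.
#' @return `read_records()`: a `tl_records` data frame.
#' @export
read_records <- function(path, task) {
  task <- match.arg(task, TASKS)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    na.strings = c("NA", ""))
  need <- task_column(task)
  if (!need %in% names(raw)) {
    stop("file lacks required column '", need, "' for task ", task)
  }
  if (!all(c("peptide", "allele") %in% names(raw))) {
    stop("file lacks required column 'peptide' or 'allele'")
  }
  num_cols <- c("affinity_nm", "half_life_hours", "imm_label",
                "recognition_frequency")
  for (cn in intersect(num_cols, names(raw))) {
    v <- raw[[cn]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad)) {
      stop("malformed numeric in column '", cn, "' at line ", bad[1L] + 1L,
           ": '", v[bad[1L]], "'")
    }
    raw[[cn]] <- parsed
  }
  for (cn in setdiff(RECORD_COLUMNS, names(raw))) raw[[cn]] <- NA
  pmhc_records(
    peptide = raw$peptide, allele = raw$allele, task = task,
    affinity_nm = raw$affinity_nm, el_label = raw$el_label,
    half_life_hours = raw$half_life_hours, imm_label = raw$imm_label,
    recognition_frequency = raw$recognition_frequency,
    source = raw$source,
    is_random_negative = !is.na(raw$is_random_negative) &
      raw$is_random_negative %in% c("TRUE", "true", "1")
  )
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  validate_records(records)
  write.table(records[, RECORD_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Thresholds used when curating stability training data
#'
#' @param strong_binder_threshold_nm affinities below this are "strong
#'   binders" (default 500 nM, the conventional cutoff).
#' @param random_negative_threshold_nm affinities above this qualify a
#'   peptide as a random negative (default 20,000 nM).
#' @return list of class `tl_filter_config`.
#' @export
filter_config <- function(strong_binder_threshold_nm = 500,
                          random_negative_threshold_nm = 20000) {
  stopifnot(strong_binder_threshold_nm < random_negative_threshold_nm)
  structure(list(strong_binder_threshold_nm = strong_binder_threshold_nm,
                 random_negative_threshold_nm = random_negative_threshold_nm),
            class = "tl_filter_config")
}

#' Map binding affinities to the \[0,1\] training scale
#'
#' `transform_affinity()` applies the log-transform conventional for
#' binding predictors, `1 - log(nM)/log(cap)`, clamped to \[0,1\]: 1 nM
#' maps to 1, the cap (default 50,000 nM) maps to 0, and the map is
#' strictly decreasing in nM below the cap. `inverse_affinity()` is its
#' exact inverse on (0, 1\].
#'
#' @param affinity_nm positive affinities in nM.
#' @param value training-scale values in \[0,1\].
#' @param cap_nm the affinity treated as "no binding" (default 50,000).
#' @return numeric vector.
#' @export
transform_affinity <- function(affinity_nm, cap_nm = 50000) {
  if (any(affinity_nm <= 0)) stop("affinity_nm must be > 0")
  pmin(pmax(1 - log(affinity_nm) / log(cap_nm), 0), 1)
}

#' @rdname transform_affinity
#' @export
inverse_affinity <- function(value, cap_nm = 50000) {
  cap_nm^(1 - value)
}

#' Map dissociation half-lives to the \[0,1\] training scale
#'
#' Saturating transform `h / (h + h0)`: 0 hours maps to 0 (the label
#' given to random negatives), `h0` hours maps to 0.5, and the map is
#' strictly increasing. `inverse_half_life()` is its exact inverse on
#' \[0, 1).
#'
#' @param h non-negative half-lives in hours.
#' @param value training-scale values in \[0, 1).
#' @param h0 half-life mapping to 0.5 (hours; default 1).
#' @return numeric vector.
#' @export
transform_half_life <- function(h, h0 = 1) {
  if (any(h < 0)) stop("half-life must be >= 0")
  h / (h + h0)
}

#' @rdname transform_half_life
#' @export
inverse_half_life <- function(value, h0 = 1) {
  h0 * value / (1 - value)
}

#' Generate proteome-derived decoys for eluted-ligand hits
#'
#' Draws, for each mass-spectrometry hit, `per_hit` random subsequences
#' from the hit's source protein (or, when a hit carries no source
#' annotation or its source is absent, from the union of the supplied
#' proteins). Decoy lengths follow the empirical length distribution of
#' the hits for the same allele, and no decoy sequence equals any hit
#' sequence of the same allele. The default `per_hit = 99` gives a
#' hit:total ratio of about 1:100.
#'
#' @param hits `tl_records` of task EL with `el_label == "hit"`.
#' @param proteins named character vector of protein sequences, an
#'   `AAStringSet`, or a FASTA file path.
#' @param per_hit decoys per hit (default 99).
#' @param seed integer seed; decoy sets are reproducible bit-for-bit.
#' @return `tl_records` of task EL with `el_label == "decoy"`.
#' @export
generate_decoys <- function(hits, proteins, per_hit = 99L, seed = 1L) {
  stopifnot(all(hits$task == "EL"), all(hits$el_label == "hit"))
  proteins <- as_protein_vector(proteins)
  if (length(proteins) == 0L) stop("no source protein sequences supplied")
  rng <- local_rng(seed)
  out_pep <- character(0)
  out_allele <- character(0)
  out_src <- character(0)
  for (al in unique(hits$allele)) {
    sub <- hits[hits$allele == al, ]
    lens <- nchar(sub$peptide)
    forbidden <- unique(toupper(sub$peptide))
    n_needed <- nrow(sub) * per_hit
    got <- character(0)
    src <- character(0)
    attempts <- 0L
    while (length(got) < n_needed) {
      attempts <- attempts + 1L
      if (attempts > 50L) {
        stop("unable to draw ", n_needed, " decoys for allele ", al)
      }
      m <- n_needed - length(got)
      want_len <- sample(lens, m, replace = TRUE)
      # per-hit source protein when annotated and present, else any protein
      hit_src <- rep_len(sub$source, m)
      use_src <- ifelse(!is.na(hit_src) & hit_src %in% names(proteins),
                        hit_src,
                        sample(names(proteins), m, replace = TRUE))
      prot_len <- nchar(proteins[use_src])
      ok <- prot_len >= want_len
      if (!any(ok)) {
        if (all(nchar(proteins) < min(lens))) {
          stop("every source protein is shorter than the shortest hit")
        }
        next
      }
      start <- floor(runif(sum(ok)) * (prot_len[ok] - want_len[ok] + 1)) + 1
      cand <- substring(proteins[use_src[ok]], start, start + want_len[ok] - 1L)
      keep <- !(toupper(cand) %in% forbidden) &
        grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), cand)
      got <- c(got, cand[keep])
      src <- c(src, use_src[ok][keep])
    }
    out_pep <- c(out_pep, got[seq_len(n_needed)])
    out_allele <- c(out_allele, rep(al, n_needed))
    out_src <- c(out_src, src[seq_len(n_needed)])
  }
  rng()
  pmhc_records(out_pep, out_allele, "EL", el_label = "decoy", source = out_src)
}

as_protein_vector <- function(proteins) {
  if (inherits(proteins, "AAStringSet")) {
    return(setNames(as.character(proteins), names(proteins)))
  }
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins)) {
    ss <- Biostrings::readAAStringSet(proteins)
    return(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  }
  if (is.character(proteins)) {
    if (is.null(names(proteins))) {
      names(proteins) <- sprintf("protein_%d", seq_along(proteins))
    }
    return(toupper(proteins))
  }
  stop("'proteins' must be a named character vector, AAStringSet, or FASTA path")
}

# Evaluate fn under a fixed seed without disturbing the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Keep only records predicted to be strong binders
#'
#' Retains records whose predicted affinity is strictly below the
#' strong-binder threshold (default 500 nM), preserving input order.
#' Used to emulate the training-data conditions of stability predictors,
#' whose non-negative instances are all strong binders.
#'
#' @param records `tl_records`.
#' @param scores_nm one predicted affinity (nM) per record.
#' @param cfg a [filter_config()].
#' @return filtered `tl_records`.
#' @export
strong_binder_filter <- function(records, scores_nm, cfg = filter_config()) {
  if (length(scores_nm) != nrow(records)) {
    stop("need exactly one score per record: got ", length(scores_nm),
         " scores for ", nrow(records), " records")
  }
  out <- records[scores_nm < cfg$strong_binder_threshold_nm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Append random negatives to a stability dataset
#'
#' Samples `n` candidate peptides whose predicted affinity exceeds the
#' random-negative threshold (default 20,000 nM) and appends them with a
#' half-life label of exactly 0 hours and `is_random_negative = TRUE`,
#' balancing the dataset with unstable examples.
#'
#' @param stab_records `tl_records` of task STAB.
#' @param candidates data frame with columns `peptide`, `allele`,
#'   `predicted_nm`.
#' @param n number of negatives to append.
#' @param cfg a [filter_config()].
#' @param seed integer seed.
#' @return augmented `tl_records`.
#' @export
add_random_negatives <- function(stab_records, candidates, n,
                                 cfg = filter_config(), seed = 1L) {
  stopifnot(all(c("peptide", "allele", "predicted_nm") %in% names(candidates)))
  eligible <- candidates[candidates$predicted_nm > cfg$random_negative_threshold_nm, ]
  if (nrow(eligible) < n) {
    stop("only ", nrow(eligible), " eligible random-negative candidates, need ",
         n, " (shortfall ", n - nrow(eligible), ")")
  }
  rng <- local_rng(seed)
  pick <- eligible[sample.int(nrow(eligible), n), ]
  rng()
  neg <- pmhc_records(pick$peptide, pick$allele, "STAB",
                      half_life_hours = 0, source = "random_negative",
                      is_random_negative = TRUE)
  out <- rbind(stab_records, neg)
  rownames(out) <- NULL
  class(out) <- c("tl_records", "data.frame")
  out
}

record_binary_label <- function(records) {
  tk <- unique(records$task)
  if (length(tk) != 1L) stop("records must hold a single task")
  switch(tk,
         EL = as.integer(records$el_label == "hit"),
         IMM = as.integer(records$imm_label >= 0.5),
         stop("task ", tk, " has no binary label"))
}

#' Equalize per-allele label balance by subsampling
#'
#' For each allele, subsamples the majority class (never oversampling)
#' so the positive fraction reaches `target_pos_fraction` within the
#' granularity of integer counts; the minority class is untouched.
#' Alleles lacking one of the two classes cannot be balanced and are
#' dropped with a warning.
#'
#' @param records `tl_records` with binary labels (task EL or IMM).
#' @param target_pos_fraction target positive fraction (default 0.5).
#' @param seed integer seed.
#' @return subsampled `tl_records` (original row order preserved).
#' @export
balance_per_allele <- function(records, target_pos_fraction = 0.5, seed = 1L) {
  out <- records[balance_indices(records, target_pos_fraction, seed), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

# Row indices balance_per_allele would keep (used by the pipelines so
# design-matrix rows can be subset in lockstep with the records).
balance_indices <- function(records, target_pos_fraction = 0.5, seed = 1L) {
  stopifnot(target_pos_fraction > 0, target_pos_fraction < 1)
  y <- record_binary_label(records)
  rng <- local_rng(seed)
  keep <- logical(nrow(records))
  t <- target_pos_fraction
  for (al in unique(records$allele)) {
    sel <- which(records$allele == al)
    pos <- sel[y[sel] == 1L]
    neg <- sel[y[sel] == 0L]
    if (length(pos) == 0L || length(neg) == 0L) {
      warning("allele ", al, " lacks one class and was dropped")
      next
    }
    frac <- length(pos) / length(sel)
    if (frac > t) {
      n_pos <- round(length(neg) * t / (1 - t))
      pos <- sample(pos, min(n_pos, length(pos)))
    } else if (frac < t) {
      n_neg <- round(length(pos) * (1 - t) / t)
      neg <- sample(neg, min(n_neg, length(neg)))
    }
    keep[c(pos, neg)] <- TRUE
  }
  rng()
  which(keep)
}

#' Replace binary immunogenicity labels with continuous strengths
#'
#' @param records `tl_records` of task IMM.
#' @param strength per-record immunogenic strength in \[0,1\].
#' @return relabelled `tl_records`; thresholding `imm_label` at 0.5
#'   recovers a binary labelling.
#' @export
relabel_continuous <- function(records, strength) {
  stopifnot(all(records$task == "IMM"), length(strength) == nrow(records))
  if (any(strength < 0 | strength > 1)) stop("strength must lie in [0, 1]")
  records$imm_label <- as.numeric(strength)
  records
}

#' Remove training records that appear in evaluation sets
#'
#' Drops every training record whose (upper-cased peptide, normalized
#' allele) pair occurs in any of the evaluation sets, preventing data
#' leakage between training and validation/test. The number of removed
#' records is attached as attribute `"removed"`. Idempotent.
#'
#' @param train `tl_records`.
#' @param eval_sets a `tl_records` data frame or list of them.
#' @return filtered `tl_records` with attribute `removed`.
#' @export
dedup_against <- function(train, eval_sets) {
  if (is.data.frame(eval_sets)) eval_sets <- list(eval_sets)
  key <- function(df) paste(toupper(df$peptide), normalize_allele(df$allele))
  bad <- unique(unlist(lapply(eval_sets, key)))
  drop <- key(train) %in% bad
  out <- train[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(drop)
  out
}
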