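#' Configuration of the synthetic pMHC data generator
#'
#' The generator emulates the statistical structure the transfer
#' protocols rely on: a position-weight-matrix binding signal dominated
#' by the anchor positions (P2 and the C-terminus), a kinetic-stability
#' signal coupled to binding with an additional contribution from
#' non-anchor middle positions, and an immunogenicity signal driven by
#' the middle, TCR-facing positions; plus configurable noise, a small
#' fraction of deliberately discordant stability records (strong
#' binders with low stability and vice versa), and per-allele label
#' imbalance.
#'
#' @param n_alleles number of synthetic alleles.
#' @param peptides_per_allele peptides drawn per allele per task.
#' @param peptide_length peptide length in residues (default 9).
#' @param pseudo_length pseudo-sequence length (default 34).
#' @param anchor_positions positions whose binding weights dominate
#'   (default 2 and the C-terminus).
#' @param middle_positions TCR-facing positions (default 4:6).
#' @param anchor_factor ratio of mean absolute anchor weight to mean
#'   absolute non-anchor weight (default 4).
#' @param affinity_noise_sd sd of the noise added to the standardized
#'   binding energy before the affinity map (default 0.3).
#' @param el_hit_quantile fraction of drawn peptides called
#'   mass-spectrometry hits (strongest binders; default 0.1).
#' @param decoys_per_hit decoys per eluted-ligand hit in simulated sets
#'   (default 9, keeping set sizes desk-scale; [generate_decoys()]
#'   itself defaults to the 99 used when curating real data).
#' @param stability_coupling strength of the binding-to-stability
#'   coupling, in \[0,1\] (default 0.8).
#' @param stability_extra_weight weight of the middle-position
#'   contribution to stability (default 0.3).
#' @param stability_noise_sd sd of stability noise (default 0.4).
#' @param discordant_fraction fraction of stability records whose
#'   latent stability is redrawn independently of binding (default
#'   0.05).
#' @param random_negative_fraction random negatives appended to a
#'   simulated stability set, as a fraction of its size (default 0.2).
#' @param half_life_scale hours corresponding to latent 0; half-lives
#'   are `half_life_scale * exp(latent)` (default 2 h).
#' @param imm_coupling strength of the binding-to-immunogenicity
#'   coupling, in \[0,1\] (default 0.8).
#' @param imm_middle_weight weight of the middle-position term in the
#'   immunogenicity signal (default 0.5).
#' @param imm_noise sd of immunogenicity noise (default 0.3).
#' @param n_donors donors used to simulate recognition frequencies
#'   (default 10).
#' @param per_allele_imbalance optional named vector allele ->
#'   target positive fraction, enforced by subsampling.
#' @param n_proteins,protein_length_meanlog,protein_length_sdlog
#'   synthetic proteome: i.i.d.-residue sequences with log-normal
#'   lengths (median ~400).
#' @param seed master seed; every generator draw derives from it.
#' @return list of class `tl_synth_config`.
#' @export
synth_config <- function(n_alleles = 5L, peptides_per_allele = 1000L,
                         peptide_length = 9L, pseudo_length = 34L,
                         anchor_positions = NULL, middle_positions = NULL,
                         anchor_factor = 4,
                         affinity_noise_sd = 0.3, el_hit_quantile = 0.1,
                         decoys_per_hit = 9L,
                         stability_coupling = 0.8,
                         stability_extra_weight = 0.3,
                         stability_noise_sd = 0.4,
                         discordant_fraction = 0.05,
                         random_negative_fraction = 0.2,
                         half_life_scale = 2,
                         imm_coupling = 0.8, imm_middle_weight = 0.5,
                         imm_noise = 0.3, n_donors = 10L,
                         per_allele_imbalance = NULL,
                         n_proteins = 200L,
                         protein_length_meanlog = log(400),
                         protein_length_sdlog = 0.5,
                         seed = 1L) {
  L <- as.integer(peptide_length)
  if (is.null(anchor_positions)) anchor_positions <- c(2L, L)
  if (is.null(middle_positions)) middle_positions <- 4:min(6L, L - 1L)
  stopifnot(n_alleles >= 1L, L >= 8L,
            stability_coupling >= 0, stability_coupling <= 1,
            imm_coupling >= 0, imm_coupling <= 1,
            el_hit_quantile > 0, el_hit_quantile < 1)
  structure(as.list(environment()), class = "tl_synth_config")
}

#' Generate synthetic alleles
#'
#' Each allele carries a distinct random pseudo-sequence, a binding
#' position-weight matrix whose mean absolute weight at the anchor
#' positions exceeds the non-anchor mean by exactly `anchor_factor`,
#' and an independent middle-position weight matrix (the TCR-contact
#' signal used by the stability and immunogenicity generators).
#'
#' @param cfg a [synth_config()].
#' @return list of `tl_synth_allele` objects (fields `name`,
#'   `pseudo_sequence`, `binding_pwm`, `middle_pwm`,
#'   `anchor_positions`, `middle_positions`).
#' @export
make_alleles <- function(cfg) {
  stopifnot(inherits(cfg, "tl_synth_config"))
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  L <- cfg$peptide_length
  lapply(seq_len(cfg$n_alleles), function(i) {
    pwm <- matrix(rnorm(L * 20L, sd = 0.25), L, 20L,
                  dimnames = list(NULL, AA_ALPHABET))
    anch <- cfg$anchor_positions
    ratio <- mean(abs(pwm[anch, ])) / mean(abs(pwm[-anch, ]))
    pwm[anch, ] <- pwm[anch, ] * (cfg$anchor_factor / ratio)
    mid <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
    mid[cfg$middle_positions, ] <- rnorm(length(cfg$middle_positions) * 20L)
    structure(list(name = sprintf("SYN-%02d", i),
                   pseudo_sequence = paste(sample(AA_ALPHABET, cfg$pseudo_length,
                                                  replace = TRUE), collapse = ""),
                   binding_pwm = pwm, middle_pwm = mid,
                   anchor_positions = anch,
                   middle_positions = cfg$middle_positions),
              class = "tl_synth_allele")
  })
}

#' Synthetic proteome
#'
#' Seeded i.i.d.-residue protein sequences with log-normal lengths
#' (median ~400 residues), used as the decoy and motif-fragmentation
#' source.
#'
#' @param cfg a [synth_config()].
#' @return named character vector of protein sequences.
#' @export
make_proteome <- function(cfg) {
  rng <- local_rng(cfg$seed + 7L)
  on.exit(rng())
  lens <- pmax(50L, round(exp(rnorm(cfg$n_proteins, cfg$protein_length_meanlog,
                                    cfg$protein_length_sdlog))))
  setNames(
    vapply(lens, function(l) paste(sample(AA_ALPHABET, l, replace = TRUE),
                                   collapse = ""), character(1L)),
    sprintf("SYNPROT_%04d", seq_len(cfg$n_proteins))
  )
}

random_peptides <- function(n, L) {
  matrix(sample(AA_ALPHABET, n * L, replace = TRUE), n, L)
}

# PWM score of peptides (character matrix n x L) standardized by the
# PWM-implied moments under uniform i.i.d. residues, so the latent
# scale is identical across independently generated batches.
pwm_latent <- function(pep_mat, pwm) {
  L <- ncol(pep_mat)
  idx <- matrix(match(pep_mat, colnames(pwm)), nrow(pep_mat), L)
  E <- rowSums(vapply(seq_len(L), function(j) pwm[j, idx[, j]],
                      numeric(nrow(pep_mat))))
  mu <- sum(rowMeans(pwm))
  v <- sum(apply(pwm, 1L, function(r) mean(r^2) - mean(r)^2))
  if (v == 0) return(E * 0)
  (E - mu) / sqrt(v)
}

latent_for_allele <- function(peptides, allele, which = c("binding", "middle")) {
  which <- match.arg(which)
  pm <- do.call(rbind, strsplit(peptides, "", fixed = TRUE))
  pwm <- if (which == "binding") allele$binding_pwm else allele$middle_pwm
  pwm_latent(pm, pwm)
}

allele_lookup <- function(alleles) {
  setNames(alleles, vapply(alleles, `[[`, character(1L), "name"))
}

#' Pseudo-sequence table of a synthetic allele panel
#'
#' @param alleles list from [make_alleles()].
#' @return named character vector usable wherever a pseudo-sequence
#'   table is expected.
#' @export
synth_pseudosequence_table <- function(alleles) {
  setNames(vapply(alleles, `[[`, character(1L), "pseudo_sequence"),
           vapply(alleles, `[[`, character(1L), "name"))
}

#' Simulate binding-affinity and eluted-ligand datasets
#'
#' For each allele, draws uniform random peptides, scores them with the
#' allele's binding PWM (standardized latent `z`), adds Gaussian noise,
#' and maps the result to nanomolar affinities via
#' `affinity_nm = 50000^(1 - plogis(z))` — the exact inverse of
#' [transform_affinity()], so couplings stay interpretable on the
#' training scale. Eluted-ligand hits are the strongest-binding
#' `el_hit_quantile` of an independent peptide draw; decoys come from
#' the synthetic proteome via [generate_decoys()].
#'
#' @param cfg a [synth_config()].
#' @param alleles list from [make_alleles()].
#' @param proteome optional proteome (default [make_proteome()]).
#' @return list with `ba` and `el` record tables (both carrying a
#'   `latent` column with the noise-free standardized binding score)
#'   and `proteome`.
#' @export
simulate_binding <- function(cfg, alleles, proteome = NULL) {
  if (is.null(proteome)) proteome <- make_proteome(cfg)
  rng <- local_rng(cfg$seed + 11L)
  ba_list <- list(); el_list <- list()
  for (al in alleles) {
    n <- cfg$peptides_per_allele
    pm <- random_peptides(n, cfg$peptide_length)
    pep <- apply(pm, 1L, paste, collapse = "")
    z <- pwm_latent(pm, al$binding_pwm)
    zn <- z + rnorm(n, sd = cfg$affinity_noise_sd)
    ba <- pmhc_records(pep, al$name, "BA",
                       affinity_nm = 50000^(1 - plogis(zn)),
                       source = "synthetic")
    ba$latent <- z
    ba_list[[al$name]] <- ba
    # independent draw for the eluted-ligand task
    pm2 <- random_peptides(n, cfg$peptide_length)
    pep2 <- apply(pm2, 1L, paste, collapse = "")
    z2 <- pwm_latent(pm2, al$binding_pwm) + rnorm(n, sd = cfg$affinity_noise_sd)
    aff2 <- 50000^(1 - plogis(z2))
    thr <- quantile(aff2, cfg$el_hit_quantile)
    hit <- aff2 <= thr
    el <- pmhc_records(pep2[hit], al$name, "EL", el_label = "hit",
                       source = sample(names(proteome), sum(hit), replace = TRUE))
    el$latent <- z2[hit]
    el_list[[al$name]] <- el
  }
  ba <- do.call(rbind, ba_list)
  hits <- do.call(rbind, el_list)
  rng()
  decoys <- generate_decoys(hits[, RECORD_COLUMNS], proteome,
                            per_hit = cfg$decoys_per_hit,
                            seed = cfg$seed + 13L)
  decoys$latent <- NA_real_
  el <- rbind(hits, decoys)
  rownames(ba) <- rownames(el) <- NULL
  list(ba = ba, el = el, proteome = proteome)
}

#' Simulate a kinetic-stability dataset
#'
#' Takes the strong binders (affinity below the strong-binder
#' threshold) of a simulated binding set — mirroring the fact that
#' stability assays require binding — and assigns half-lives from a
#' latent `stability_coupling * z + stability_extra_weight * m +
#' noise`, where `z` is the binding latent and `m` the standardized
#' middle-position (non-anchor) contribution. A `discordant_fraction`
#' of records get an independently redrawn latent, reproducing the
#' observed strong-binders-with-low-stability outliers. Random
#' negatives (affinity > 20,000 nM, half-life 0) are appended via
#' [add_random_negatives()].
#'
#' @param cfg a [synth_config()].
#' @param alleles list from [make_alleles()].
#' @param binding result of [simulate_binding()] (its `ba` table).
#' @return `tl_records` of task STAB with `latent` column.
#' @export
simulate_stability <- function(cfg, alleles, binding) {
  ba <- binding$ba
  lk <- allele_lookup(alleles)
  fc <- filter_config()
  strong <- ba[ba$affinity_nm < fc$strong_binder_threshold_nm, , drop = FALSE]
  rng <- local_rng(cfg$seed + 17L)
  m <- numeric(nrow(strong))
  for (aln in unique(strong$allele)) {
    sel <- strong$allele == aln
    m[sel] <- latent_for_allele(strong$peptide[sel], lk[[aln]], "middle")
  }
  n <- nrow(strong)
  lat <- cfg$stability_coupling * strong$latent +
    cfg$stability_extra_weight * m +
    rnorm(n, sd = cfg$stability_noise_sd)
  if (cfg$discordant_fraction > 0) {
    nd <- round(n * cfg$discordant_fraction)
    if (nd > 0) {
      idx <- sample.int(n, nd)
      lat[idx] <- rnorm(nd)
    }
  }
  stab <- pmhc_records(strong$peptide, strong$allele, "STAB",
                       half_life_hours = cfg$half_life_scale * exp(lat),
                       source = "synthetic")
  stab$latent <- lat
  rng()
  n_neg <- floor(nrow(stab) * cfg$random_negative_fraction)
  if (n_neg > 0) {
    cand <- random_negative_candidates(cfg, alleles, n_neg, fc,
                                       seed = cfg$seed + 29L)
    stab0 <- stab[, RECORD_COLUMNS]
    class(stab0) <- c("tl_records", "data.frame")
    out <- add_random_negatives(stab0, cand, n_neg, fc,
                                seed = cfg$seed + 19L)
    out$latent <- c(stab$latent, rep(NA_real_, n_neg))
    return(out)
  }
  stab
}

# Draw fresh random peptides, score their simulated affinity, and keep
# scanning until at least n_needed non-binders (predicted affinity above
# the random-negative threshold) are found across the allele panel.
random_negative_candidates <- function(cfg, alleles, n_needed, fc, seed) {
  rng <- local_rng(seed)
  on.exit(rng())
  cand <- list()
  total <- 0L
  for (attempt in 1:40) {
    for (al in alleles) {
      m <- max(2000L, n_needed)
      pm <- random_peptides(m, cfg$peptide_length)
      z <- pwm_latent(pm, al$binding_pwm) + rnorm(m, sd = cfg$affinity_noise_sd)
      nm <- 50000^(1 - plogis(z))
      keep <- nm > fc$random_negative_threshold_nm
      if (any(keep)) {
        cand[[length(cand) + 1L]] <-
          data.frame(peptide = apply(pm[keep, , drop = FALSE], 1L, paste,
                                     collapse = ""),
                     allele = al$name, predicted_nm = nm[keep])
        total <- total + sum(keep)
      }
    }
    if (total >= n_needed) break
  }
  if (total < n_needed) {
    stop("could not find ", n_needed, " random-negative candidates (found ",
         total, ")")
  }
  do.call(rbind, cand)
}

#' Simulate an immunogenicity dataset
#'
#' Draws peptides per allele and sets
#' `P(immunogenic) = plogis(2 * (imm_coupling * z + imm_middle_weight *
#' m + noise))`, with `z` the standardized binding latent and `m` the
#' middle-position term — immunogenicity is driven by the TCR-facing
#' middle residues on top of presentation. The binary `imm_label` is
#' sampled from that probability; the probability itself is returned in
#' column `strength` (the continuous label for
#' [relabel_continuous()]), and a donor recognition frequency is
#' simulated as positive responses over `n_donors` tested donors.
#' Per-allele positive fractions are forced toward
#' `cfg$per_allele_imbalance` (when set) by subsampling the majority
#' class.
#'
#' @param cfg a [synth_config()].
#' @param alleles list from [make_alleles()].
#' @return `tl_records` of task IMM with extra columns `strength`,
#'   `latent`.
#' @export
simulate_immunogenicity <- function(cfg, alleles) {
  rng <- local_rng(cfg$seed + 23L)
  on.exit(rng())
  out <- list()
  for (al in alleles) {
    n <- cfg$peptides_per_allele
    pm <- random_peptides(n, cfg$peptide_length)
    pep <- apply(pm, 1L, paste, collapse = "")
    z <- pwm_latent(pm, al$binding_pwm)
    m <- pwm_latent(pm, al$middle_pwm)
    lin <- cfg$imm_coupling * z + cfg$imm_middle_weight * m +
      rnorm(n, sd = cfg$imm_noise)
    p <- plogis(2 * lin)
    y <- as.integer(runif(n) < p)
    rec <- pmhc_records(pep, al$name, "IMM", imm_label = y,
                        recognition_frequency =
                          stats::rbinom(n, cfg$n_donors, p) / cfg$n_donors,
                        source = "synthetic")
    rec$strength <- p
    rec$latent <- z
    target <- cfg$per_allele_imbalance[al$name]
    if (!is.null(cfg$per_allele_imbalance) && !is.na(target)) {
      rec <- force_positive_fraction(rec, target)
    }
    out[[al$name]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Subsample the majority side so the realized positive fraction matches
# the target; errors when the needed class is absent.
force_positive_fraction <- function(rec, target) {
  stopifnot(target > 0, target < 1)
  y <- rec$imm_label >= 0.5
  pos <- which(y); neg <- which(!y)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("infeasible imbalance target ", target, " for allele ",
         rec$allele[1L], ": a class is empty")
  }
  frac <- length(pos) / nrow(rec)
  if (frac > target) {
    pos <- sample(pos, max(1L, round(length(neg) * target / (1 - target))))
  } else if (frac < target) {
    neg <- sample(neg, max(1L, round(length(pos) * (1 - target) / target)))
  }
  out <- rec[sort(c(pos, neg)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Encode a record table against a synthetic allele panel
#'
#' Convenience wrapper joining records to their alleles'
#' pseudo-sequences and calling [encode_dataset()].
#'
#' @param records `tl_records`.
#' @param alleles list from [make_alleles()] (or a named
#'   pseudo-sequence vector).
#' @param scheme a [encoding_scheme()].
#' @param max_len peptide positions (default the records' maximum
#'   length).
#' @return numeric design matrix.
#' @export
encode_records <- function(records, alleles, scheme = encoding_scheme(),
                           max_len = NULL) {
  tab <- if (is.character(alleles)) alleles else synth_pseudosequence_table(alleles)
  if (is.null(max_len)) max_len <- max(nchar(records$peptide))
  ps <- tab[records$allele]
  if (anyNA(ps)) {
    stop("no pseudo-sequence for allele(s): ",
         paste(unique(records$allele[is.na(ps)]), collapse = ", "))
  }
  encode_dataset(records$peptide, unname(ps), scheme, max_len)
}

#' Training targets for a record table
#'
#' Maps task labels to the \[0,1\] scale of the matching head:
#' affinities via [transform_affinity()], half-lives via
#' [transform_half_life()], eluted-ligand hits/decoys to 1/0,
#' immunogenicity labels as-is.
#'
#' @param records `tl_records` of a single task.
#' @param h0 half-life midpoint passed to [transform_half_life()].
#' @return data frame with columns `value`, `head` suitable for
#'   [train_model()].
#' @export
record_targets <- function(records, h0 = 1) {
  tk <- unique(records$task)
  stopifnot(length(tk) == 1L)
  value <- switch(tk,
    BA = transform_affinity(records$affinity_nm),
    EL = as.numeric(records$el_label == "hit"),
    STAB = transform_half_life(records$half_life_hours, h0),
    IMM = records$imm_label)
  data.frame(value = value, head = tk, stringsAsFactors = FALSE)
}
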