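# Independent oracles, written against the stated rules rather than the
# package's code paths, plus small fixture builders.

# Brute-force maximal-primitive-tract enumerator: tests every (start, unit
# length) anchor directly by substring comparison.
oracle_scan_one <- function(seq, chrom = "chr", min_unit = 1L, max_unit = 5L,
                            min_copies = 7L, max_copies = 13L,
                            enforce_upper = TRUE) {
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (u in min_unit:max_unit) {
    if (L < u * min_copies) next
    for (i in seq_len(L - u * min_copies + 1L)) {
      unit <- substr(seq, i, i + u - 1L)
      if (grepl("[^ACGT]", unit)) next
      # left-maximality: anchor only where the period-u pattern cannot
      # extend one base left
      if (i > 1L && ch[i - 1L] == ch[i + u - 1L]) next
      # primitivity of the starting frame
      prim <- TRUE
      if (u > 1L) {
        for (d in seq_len(u - 1L)) {
          if (u %% d == 0L &&
              unit == strrep(substr(unit, 1L, d), u %/% d)) {
            prim <- FALSE
            break
          }
        }
      }
      if (!prim) next
      cc <- 1L
      while (i + (cc + 1L) * u - 1L <= L &&
             substr(seq, i + cc * u, i + (cc + 1L) * u - 1L) == unit) {
        cc <- cc + 1L
      }
      if (cc < min_copies) next
      if (enforce_upper && cc > max_copies) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = i - 1L, end = i - 1L + cc * u,
        unit = oracle_min_rotation(unit), unit_len = u, copies = cc,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), unit = character(),
                      unit_len = integer(), copies = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$unit_len), , drop = FALSE]
}

oracle_min_rotation <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(unit)
  doubled <- paste0(unit, unit)
  min(vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), ""))
}

scan_as_key <- function(df) {
  sort(paste(df$chrom, df$start, df$end, df$unit, df$copies, sep = "|"))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"),
                       weights = NULL) {
  paste0(sample(alphabet, n, replace = TRUE, prob = weights), collapse = "")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Independent paired-call recomputation from two histograms (named integer
# vectors: names = lengths, values = family counts).
oracle_paired_call <- function(tumor_hist, normal_hist, tau = 0.10,
                               min_cov = 20L, min_allele_frac = 0.05) {
  cov_t <- sum(tumor_hist)
  cov_n <- sum(normal_hist)
  if (cov_t < min_cov || cov_n < min_cov) {
    return(list(statistic = NA_real_, unstable = FALSE, no_call = TRUE))
  }
  supp <- as.integer(names(normal_hist)[normal_hist / cov_n >= min_allele_frac])
  lens <- as.integer(names(tumor_hist))
  stat <- sum(tumor_hist[!(lens %in% supp)]) / cov_t
  list(statistic = stat, unstable = stat >= tau, no_call = FALSE)
}

hist_to_profile <- function(hist, sample_id, locus_id) {
  tibble::tibble(
    sample_id = sample_id, locus_id = locus_id,
    tract_len_units = as.integer(names(hist)),
    family_count = as.integer(unname(hist))
  )
}

random_hist <- function(rng_lengths = 8:14, max_lens = 3L,
                        count_range = c(0L, 80L)) {
  k <- sample(seq_len(max_lens), 1L)
  lens <- sample(rng_lengths, k)
  counts <- sample(count_range[1]:count_range[2], k, replace = TRUE)
  keep <- counts > 0
  if (!any(keep)) {
    lens <- lens[1]
    counts <- 1L
  } else {
    lens <- lens[keep]
    counts <- counts[keep]
  }
  stats::setNames(as.integer(counts), as.integer(lens))
}

# Independent exhaustive panel-search oracle implementing the documented
# scoring and tie-break rules with plain loops.
oracle_optimize <- function(U, labels, k_min = 2L, k_max = 8L,
                            min_unstable = 2L,
                            require_full_specificity = TRUE) {
  cand <- sort(colnames(U))
  pos <- labels == "dMMR"
  neg <- labels == "pMMR"
  best <- NULL
  for (k in k_min:min(k_max, length(cand))) {
    combs <- combn(cand, k)
    for (j in seq_len(ncol(combs))) {
      ids <- combs[, j]
      cnt <- rowSums(U[, ids, drop = FALSE])
      hit <- cnt >= min_unstable
      sens <- mean(hit[pos])
      spec <- mean(!hit[neg])
      cur <- list(ids = sort(ids), sens = sens, spec = spec)
      if (is.null(best)) {
        best <- cur
        next
      }
      if (require_full_specificity) {
        f_cur <- spec == 1
        f_best <- best$spec == 1
        if (f_cur != f_best) {
          if (f_cur) best <- cur
          next
        }
      }
      if (spec != best$spec) {
        if (spec > best$spec) best <- cur
        next
      }
      if (sens != best$sens) {
        if (sens > best$sens) best <- cur
        next
      }
      if (length(cur$ids) != length(best$ids)) {
        if (length(cur$ids) < length(best$ids)) best <- cur
        next
      }
      if (paste(cur$ids, collapse = ",") < paste(best$ids, collapse = ",")) {
        best <- cur
      }
    }
  }
  best
}

# Random call matrix for selection/optimization tests.
random_call_matrix <- function(n_tumors, locus_ids, p_unstable = 0.3,
                               p_nocall = 0.05, frac_dmmr = 0.5) {
  sample_ids <- sprintf("T%03d", seq_len(n_tumors))
  n_dmmr <- round(frac_dmmr * n_tumors)
  labels <- c(rep("dMMR", n_dmmr), rep("pMMR", n_tumors - n_dmmr))
  calls <- tidyr::expand_grid(sample_id = sample_ids, locus_id = locus_ids)
  calls$no_call <- runif(nrow(calls)) < p_nocall
  calls$unstable <- !calls$no_call & runif(nrow(calls)) < p_unstable
  calls$statistic <- ifelse(calls$no_call, NA_real_,
                            ifelse(calls$unstable, 0.5, 0.0))
  samples <- tibble::tibble(
    sample_id = sample_ids, patient_id = sample_ids, tissue = "tumor",
    mmr_status = labels, cohort = "train"
  )
  build_call_matrix(calls, samples)
}

# Small fully-simulated cohort ready for calling, shared across tests.
small_cohort <- function(seed = 42L, n_paired = 12L, n_unmatched = 6L,
                         n_loci = 30L, n_informative = 4L, ...) {
  cf <- simulation_config(seed = seed, n_paired_patients = n_paired,
                          n_unmatched_tumors = n_unmatched,
                          n_loci = n_loci, n_informative = n_informative,
                          ...)
  simulate_cohort(cf)
}
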