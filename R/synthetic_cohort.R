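#' Simulation configuration for a synthetic UMI-Seq MSI cohort
#'
#' Bundles and validates every knob of the cohort generator. Defaults emulate
#' a matched tumor/normal FFPE study profiled by UMI-tagged amplicon
#' sequencing at mononucleotide-dominated microsatellite loci: dMMR tumors
#' carry somatic repeat-length shifts at a planted informative locus subset,
#' pMMR tumors are largely stable, and PCR stutter perturbs every read by
#' one repeat unit at rate `stutter_eps`. The study design the generator
#' stands in for gives no noise or purity parameters, so these defaults are
#' explicit stand-ins (see the methods vignette).
#'
#' @param seed Master seed; all randomness derives from it via per-stream
#'   hashing, so adding samples does not perturb existing ones.
#' @param n_paired_patients Patients with one tumor and one matched normal
#'   (assigned to the `train` cohort).
#' @param n_unmatched_tumors Tumor-only patients (the `validation` cohort).
#' @param frac_dmmr Fraction of tumors that are mismatch-repair deficient;
#'   class counts are deterministic (`round(frac_dmmr * n)`).
#' @param n_loci Catalog size; `n_informative` of them (mononucleotide,
#'   non-polymorphic) carry true somatic instability signal in dMMR tumors.
#' @param n_informative Number of planted informative loci.
#' @param p_unstable_dmmr,p_unstable_pmmr Per-informative-locus probability
#'   that a dMMR (resp. pMMR) tumor is truly unstable there.
#' @param p_decoy_unstable Instability probability at non-informative loci.
#' @param stutter_eps Per-read probability of a +/-1-unit slippage (split
#'   equally up/down).
#' @param purity Fraction of tumor-derived molecules in a tumor sample.
#' @param shift_set Allowed somatic shifts, in repeat units (never 0).
#' @param families_per_locus Mean UMI families per (sample, locus); Poisson.
#' @param reads_per_family Rate parameter of the zero-truncated Poisson for
#'   family size.
#' @param polymorphic_frac Fraction of loci given germline allele-length
#'   variation across patients.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_paired_patients = 100L,
                              n_unmatched_tumors = 60L,
                              frac_dmmr = 0.5,
                              n_loci = 200L,
                              n_informative = 8L,
                              p_unstable_dmmr = 0.85,
                              p_unstable_pmmr = 0.02,
                              p_decoy_unstable = 0.01,
                              stutter_eps = 0.08,
                              purity = 0.6,
                              shift_set = c(-3L, -2L, -1L, 1L, 2L),
                              families_per_locus = 60,
                              reads_per_family = 4,
                              polymorphic_frac = 0.05) {
  probs <- c(frac_dmmr, p_unstable_dmmr, p_unstable_pmmr, p_decoy_unstable,
             stutter_eps, purity, polymorphic_frac)
  if (any(probs < 0 | probs > 1)) {
    abort("all probability/fraction parameters must lie in [0, 1]")
  }
  if (n_informative > n_loci) abort("`n_informative` must not exceed `n_loci`")
  if (families_per_locus <= 0 || reads_per_family <= 0) {
    abort("`families_per_locus` and `reads_per_family` must be positive")
  }
  if (any(shift_set == 0L)) abort("`shift_set` must not contain 0")
  if (n_paired_patients < 0 || n_unmatched_tumors < 0) {
    abort("cohort sizes must be non-negative")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_paired_patients = as.integer(n_paired_patients),
      n_unmatched_tumors = as.integer(n_unmatched_tumors),
      frac_dmmr = frac_dmmr,
      n_loci = as.integer(n_loci),
      n_informative = as.integer(n_informative),
      p_unstable_dmmr = p_unstable_dmmr,
      p_unstable_pmmr = p_unstable_pmmr,
      p_decoy_unstable = p_decoy_unstable,
      stutter_eps = stutter_eps,
      purity = purity,
      shift_set = as.integer(shift_set),
      families_per_locus = families_per_locus,
      reads_per_family = reads_per_family,
      polymorphic_frac = polymorphic_frac
    ),
    class = "simulation_config"
  )
}

# deterministic 31-bit string hash; used to derive independent substream seeds
# from the master seed so each (stream, sample, locus) gets its own RNG state.
substream_seed <- function(master, ...) {
  s <- paste(..., sep = "\r")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}

# zero-truncated Poisson via inverse CDF conditioned on X >= 1
rztpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

#' Build a deterministic synthetic microsatellite locus catalog
#'
#' Lays out `n_loci` non-overlapping repeat tracts on a virtual contig.
#' `frac_mono` of them are mononucleotide (unit length 1); the remainder draw
#' primitive units of 2-5 bp. Copy numbers are uniform on 7-13, matching the
#' discovery window of [scan_reference()].
#'
#' @param n_loci Number of loci.
#' @param seed Integer seed (the catalog is a pure function of its arguments).
#' @param frac_mono Fraction of mononucleotide loci.
#' @return A catalog tibble in [scan_reference()] layout, with synthetic
#'   `gene_label`s.
#' @export
synth_locus_catalog <- function(n_loci, seed = 1L, frac_mono = 0.7) {
  stopifnot(n_loci >= 0)
  if (n_loci == 0L) return(empty_catalog())
  set.seed(substream_seed(seed, "catalog"))
  multi_units <- c("AC", "AG", "AT", "CG", "AAC", "AAG", "AAT", "ACC",
                   "AAAC", "AAAG", "AAAT", "AAAAC", "AAAAG", "AAAAT")
  n_mono <- round(frac_mono * n_loci)
  unit <- character(n_loci)
  mono_idx <- seq_len(n_mono)
  unit[mono_idx] <- sample(c("A", "C", "G", "T"), n_mono, replace = TRUE)
  if (n_mono < n_loci) {
    unit[-mono_idx] <- sample(multi_units, n_loci - n_mono, replace = TRUE)
  }
  # shuffle so mono/multi loci interleave along the contig
  unit <- unit[sample.int(n_loci)]
  copies <- sample(7:13, n_loci, replace = TRUE)
  unit_len <- nchar(unit)
  tract_len <- unit_len * copies
  gap <- 50L
  start <- cumsum(c(0L, head(tract_len + gap, -1L)))
  end <- start + tract_len
  tibble::tibble(
    locus_id = paste0("chrS:", start, "-", end, ":", unit),
    chrom = "chrS",
    start = as.integer(start),
    end = as.integer(end),
    unit = unit,
    unit_len = as.integer(unit_len),
    copies = as.integer(copies),
    gene_label = sprintf("G%04d", seq_len(n_loci))
  )
}

#' Simulate UMI-tagged reads for one sample at one locus
#'
#' Each UMI family corresponds to one input molecule. When `somatic_shift` is
#' non-zero, a family derives from the shifted (tumor) allele with probability
#' `purity`, otherwise from the germline allele. Every read in a family then
#' reports the molecule's tract length exactly, or +/-1 unit with probability
#' `stutter_eps` (split equally up and down; lengths are clamped at 1).
#' Family sizes are zero-truncated Poisson. Draws come from the current RNG
#' state; seed beforehand for reproducibility.
#'
#' @param germline_len Germline tract length in repeat units (>= 2).
#' @param somatic_shift Somatic length shift in units (0 = stable locus);
#'   `germline_len + somatic_shift` must be >= 1.
#' @param purity Fraction of tumor-derived molecules.
#' @param stutter_eps Per-read +/-1 slippage probability.
#' @param n_families Number of UMI families to emit.
#' @param reads_per_family_mean Zero-truncated Poisson rate for family size.
#' @param sample_id,locus_id Identifiers stamped on the observations.
#' @return A tibble of UMI observations: `sample_id`, `locus_id`, `umi`,
#'   `tract_len_units`.
#' @examples
#' set.seed(1)
#' simulate_locus_reads(10, somatic_shift = -2, purity = 1,
#'                      stutter_eps = 0, n_families = 3)
#' @export
simulate_locus_reads <- function(germline_len, somatic_shift = 0L,
                                 purity = 0.6, stutter_eps = 0.08,
                                 n_families = 60L, reads_per_family_mean = 4,
                                 sample_id = "S1", locus_id = "L1") {
  if (germline_len < 2) abort("`germline_len` must be >= 2")
  if (somatic_shift != 0 && germline_len + somatic_shift < 1) {
    abort("`germline_len + somatic_shift` must be >= 1")
  }
  if (purity < 0 || purity > 1 || stutter_eps < 0 || stutter_eps > 1) {
    abort("`purity` and `stutter_eps` must lie in [0, 1]")
  }
  if (n_families < 0 || reads_per_family_mean <= 0) {
    abort("`n_families` must be >= 0 and `reads_per_family_mean` > 0")
  }
  gen <- draw_locus_reads(germline_len, somatic_shift, purity, stutter_eps,
                          n_families, reads_per_family_mean)
  tibble::tibble(
    sample_id = sample_id,
    locus_id = locus_id,
    umi = rep(sprintf("U%05d", seq_len(n_families)), gen$sizes),
    tract_len_units = gen$lens
  )
}

# RNG-consuming core shared by simulate_locus_reads() and simulate_cohort();
# draw order is part of the determinism contract.
draw_locus_reads <- function(germline_len, somatic_shift, purity, stutter_eps,
                             n_families, reads_per_family_mean) {
  if (n_families == 0L) {
    return(list(sizes = integer(), lens = integer()))
  }
  sizes <- rztpois(n_families, reads_per_family_mean)
  if (somatic_shift != 0) {
    shifted <- runif(n_families) < purity
    mol_len <- germline_len + ifelse(shifted, somatic_shift, 0L)
  } else {
    mol_len <- rep.int(germline_len, n_families)
  }
  lens <- rep(as.integer(mol_len), sizes)
  if (stutter_eps > 0) {
    u <- runif(length(lens))
    lens <- lens + (u < stutter_eps / 2) - (u >= stutter_eps / 2 & u < stutter_eps)
    lens <- pmax(lens, 1L)
  }
  list(sizes = as.integer(sizes), lens = as.integer(lens))
}

#' Simulate a full synthetic UMI-Seq cohort
#'
#' Generates matched tumor/normal pairs (cohort `train`) and unmatched tumors
#' (cohort `validation`) with dMMR/pMMR truth labels, a locus catalog, the
#' per-read UMI observation table, and the ground truth needed for
#' parameter-recovery tests. The output is a pure function of
#' `config$seed`: each (sample, locus) pair draws from its own hashed RNG
#' substream, so enlarging the cohort leaves existing samples' reads
#' untouched.
#'
#' Mechanics per tumor and locus: informative loci draw a true-instability
#' Bernoulli with `p_unstable_dmmr` or `p_unstable_pmmr` by MMR status, decoy
#' loci with `p_decoy_unstable`; unstable draws pick a somatic shift from
#' `shift_set` (restricted to keep tract lengths >= 1). Normals never carry
#' somatic shifts. `polymorphic_frac` of the non-informative loci are
#' germline-polymorphic: each patient has a 50% chance of a +/-1- or
#' +/-2-unit germline offset there, giving the downstream polymorphism filter
#' real signal to remove.
#'
#' @param config A [simulation_config()].
#' @param catalog Optional pre-built locus catalog (e.g. from a previous
#'   cohort) so two cohorts share loci; defaults to
#'   [synth_locus_catalog()]`(config$n_loci, config$seed)`.
#' @param informative_locus_ids Optional fixed informative set (must be
#'   catalog mononucleotide loci); defaults to a seeded draw.
#' @return A list of class `msi_cohort` with elements `samples` (sample
#'   sheet tibble), `catalog`, `reads` (UMI observation tibble), and `truth`
#'   (list: `informative_locus_ids`, `polymorphic_locus_ids`, `shifts` tibble
#'   of planted somatic shifts, `germline` tibble of per-patient tract
#'   lengths).
#' @export
simulate_cohort <- function(config, catalog = NULL,
                            informative_locus_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  if (is.null(catalog)) {
    catalog <- synth_locus_catalog(cf$n_loci, seed = cf$seed)
  }
  n_loci <- nrow(catalog)

  samples <- build_sample_sheet(cf)

  mono_ids <- catalog$locus_id[catalog$unit_len == 1L]
  if (is.null(informative_locus_ids)) {
    if (cf$n_informative > length(mono_ids)) {
      abort("not enough mononucleotide loci for `n_informative`")
    }
    set.seed(substream_seed(cf$seed, "informative"))
    informative_locus_ids <- sort(sample(mono_ids, cf$n_informative))
  } else {
    if (!all(informative_locus_ids %in% catalog$locus_id)) {
      abort("`informative_locus_ids` must be catalog loci")
    }
  }

  set.seed(substream_seed(cf$seed, "polymorphic"))
  poly_pool <- setdiff(catalog$locus_id, informative_locus_ids)
  n_poly <- min(round(cf$polymorphic_frac * n_loci), length(poly_pool))
  polymorphic_locus_ids <- sort(sample(poly_pool, n_poly))

  patients <- unique(samples$patient_id)
  germline <- build_germline_table(cf, catalog, patients, polymorphic_locus_ids)

  sim <- simulate_reads_and_shifts(cf, catalog, samples, germline,
                                   informative_locus_ids)

  structure(
    list(
      samples = samples,
      catalog = catalog,
      reads = sim$reads,
      truth = list(
        informative_locus_ids = informative_locus_ids,
        polymorphic_locus_ids = polymorphic_locus_ids,
        shifts = sim$shifts,
        germline = germline
      )
    ),
    class = "msi_cohort"
  )
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat("<msi_cohort>\n")
  cat("  samples: ", nrow(x$samples),
      " (", sum(x$samples$tissue == "tumor"), " tumors, ",
      sum(x$samples$tissue == "normal"), " normals)\n", sep = "")
  cat("  loci:    ", nrow(x$catalog),
      " (", length(x$truth$informative_locus_ids), " informative, ",
      length(x$truth$polymorphic_locus_ids), " polymorphic)\n", sep = "")
  cat("  reads:   ", nrow(x$reads), "\n", sep = "")
  invisible(x)
}

# MMR labels are assigned by proportional fill over the patient index:
# deterministic class counts (floor(n * frac) == round counts at the default
# fractions) and prefix-stable, so enlarging a cohort never relabels an
# existing patient (labels feed the read substreams).
mmr_fill <- function(n, frac) {
  i <- seq_len(n)
  ifelse(floor(i * frac) - floor((i - 1) * frac) == 1, "dMMR", "pMMR")
}

build_sample_sheet <- function(cf) {
  rows <- list()
  if (cf$n_paired_patients > 0L) {
    pid <- sprintf("P%04d", seq_len(cf$n_paired_patients))
    mmr <- mmr_fill(cf$n_paired_patients, cf$frac_dmmr)
    rows$paired <- tibble::tibble(
      sample_id = c(paste0(pid, "-T"), paste0(pid, "-N")),
      patient_id = c(pid, pid),
      tissue = rep(c("tumor", "normal"), each = cf$n_paired_patients),
      mmr_status = c(mmr, mmr),
      cohort = "train"
    )
  }
  if (cf$n_unmatched_tumors > 0L) {
    vid <- sprintf("V%04d", seq_len(cf$n_unmatched_tumors))
    mmr <- mmr_fill(cf$n_unmatched_tumors, cf$frac_dmmr)
    rows$unmatched <- tibble::tibble(
      sample_id = paste0(vid, "-T"),
      patient_id = vid,
      tissue = "tumor",
      mmr_status = mmr,
      cohort = "validation"
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(sample_id = character(), patient_id = character(),
                          tissue = character(), mmr_status = character(),
                          cohort = character()))
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$patient_id, .data$tissue)
}

# Germline tract length per (patient, locus). Polymorphic loci: each patient
# has prob 0.5 of an offset drawn uniformly from {-2,-1,+1,+2}; draws are
# prefix-stable in the patient index so adding patients never changes
# existing germlines.
build_germline_table <- function(cf, catalog, patients, polymorphic_locus_ids) {
  n_pat <- length(patients)
  base <- tidyr::expand_grid(patient_id = patients,
                             locus_id = catalog$locus_id) |>
    dplyr::left_join(
      dplyr::select(catalog, "locus_id", germline_len = "copies"),
      by = "locus_id"
    )
  if (n_pat == 0L || length(polymorphic_locus_ids) == 0L) return(base)
  offsets <- purrr::map(polymorphic_locus_ids, function(lid) {
    set.seed(substream_seed(cf$seed, "germline", lid))
    u_carry <- runif(n_pat)
    u_off <- runif(n_pat)
    off <- ifelse(u_carry < 0.5, 0L,
                  c(-2L, -1L, 1L, 2L)[ceiling(u_off * 4)])
    tibble::tibble(patient_id = patients, locus_id = lid,
                   offset = as.integer(off))
  }) |> dplyr::bind_rows()
  base |>
    dplyr::left_join(offsets, by = c("patient_id", "locus_id")) |>
    dplyr::mutate(
      germline_len = pmax(.data$germline_len +
                            dplyr::coalesce(.data$offset, 0L), 2L)
    ) |>
    dplyr::select(-"offset")
}

# Hot loop: one hashed RNG substream per (sample, locus). Draw order within a
# substream: instability Bernoulli, shift choice, family count, then the
# read-level draws of draw_locus_reads().
simulate_reads_and_shifts <- function(cf, catalog, samples, germline,
                                      informative_locus_ids) {
  locus_ids <- catalog$locus_id
  n_loci <- length(locus_ids)
  is_inf <- locus_ids %in% informative_locus_ids

  # germline lookup matrix: patients x loci
  patients <- unique(samples$patient_id)
  gmat <- matrix(NA_integer_, nrow = length(patients), ncol = n_loci,
                 dimnames = list(patients, locus_ids))
  gmat[cbind(match(germline$patient_id, patients),
             match(germline$locus_id, locus_ids))] <- germline$germline_len

  n_pairs <- nrow(samples) * n_loci
  out_sizes <- vector("list", n_pairs)
  out_lens <- vector("list", n_pairs)
  pair_sample <- character(n_pairs); pair_locus <- character(n_pairs)
  shift_rows <- list()
  k <- 0L
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    pid <- samples$patient_id[si]
    is_tumor <- samples$tissue[si] == "tumor"
    p_inf <- if (samples$mmr_status[si] == "dMMR") cf$p_unstable_dmmr else cf$p_unstable_pmmr
    prow <- match(pid, patients)
    for (li in seq_len(n_loci)) {
      lid <- locus_ids[li]
      set.seed(substream_seed(cf$seed, "reads", sid, lid))
      g <- gmat[prow, li]
      shift <- 0L
      if (is_tumor) {
        p <- if (is_inf[li]) p_inf else cf$p_decoy_unstable
        if (runif(1) < p) {
          ok <- cf$shift_set[g + cf$shift_set >= 1L]
          if (length(ok) > 0L) {
            shift <- ok[ceiling(runif(1) * length(ok))]
          }
        }
      }
      n_fam <- rpois(1, cf$families_per_locus)
      gen <- draw_locus_reads(g, shift, cf$purity, cf$stutter_eps,
                              n_fam, cf$reads_per_family)
      k <- k + 1L
      out_sizes[[k]] <- gen$sizes
      out_lens[[k]] <- gen$lens
      pair_sample[k] <- sid
      pair_locus[k] <- lid
      if (shift != 0L) {
        shift_rows[[length(shift_rows) + 1L]] <-
          list(sample_id = sid, locus_id = lid, shift = shift)
      }
    }
  }
  n_reads <- vapply(out_sizes[seq_len(k)], sum, integer(1))
  reads <- tibble::tibble(
    sample_id = rep(pair_sample[seq_len(k)], n_reads),
    locus_id = rep(pair_locus[seq_len(k)], n_reads),
    umi = unlist(purrr::map(out_sizes[seq_len(k)], function(s) {
      rep(sprintf("U%05d", seq_along(s)), s)
    }), use.names = FALSE) %||% character(0),
    tract_len_units = unlist(out_lens[seq_len(k)], use.names = FALSE) %||% integer(0)
  )
  shifts <- if (length(shift_rows) > 0L) {
    dplyr::bind_rows(shift_rows)
  } else {
    tibble::tibble(sample_id = character(), locus_id = character(),
                   shift = integer())
  }
  list(reads = reads, shifts = shifts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write cohort tables to a directory
#'
#' Emits the sample sheet, UMI observation table, locus catalog (BED + TSV)
#' and ground-truth JSON as plain-text files.
#'
#' @param cohort An `msi_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "msi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(cohort$reads, file.path(dir, "reads.tsv"))
  write_locus_catalog(cohort$catalog,
                      file.path(dir, "loci.bed"), file.path(dir, "loci.tsv"))
  jsonlite::write_json(
    list(
      informative_locus_ids = cohort$truth$informative_locus_ids,
      polymorphic_locus_ids = cohort$truth$polymorphic_locus_ids,
      shifts = cohort$truth$shifts,
      germline = cohort$truth$germline
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}
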