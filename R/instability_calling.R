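#' Allele-length support of a normal profile
#'
#' The support is the set of tract lengths backed by at least
#' `min_allele_frac` of the sample's consensus families at the locus —
#' everything a normal plausibly carries (germline alleles plus residual
#' noise above the floor). Tumor lengths outside this set are "novel".
#'
#' @param profile Profile tibble rows for one (sample, locus):
#'   `tract_len_units`, `family_count`.
#' @param min_allele_frac Minimum family fraction for a length to enter the
#'   support (boundary inclusive).
#' @return Sorted integer vector of supported tract lengths.
#' @examples
#' normal_support(tibble::tibble(tract_len_units = c(10L, 11L),
#'                               family_count = c(95L, 5L)))  # 10 and 11
#' @export
normal_support <- function(profile, min_allele_frac = 0.05) {
  if (nrow(profile) == 0L || sum(profile$family_count) == 0L) {
    abort("`profile` must contain at least one family")
  }
  total <- sum(profile$family_count)
  sort(unique(profile$tract_len_units[
    profile$family_count / total >= min_allele_frac
  ]))
}

# per-(sample, locus) support table, vectorized over a long profile tibble
support_table <- function(profiles, min_allele_frac = 0.05) {
  profiles |>
    dplyr::group_by(.data$sample_id, .data$locus_id) |>
    dplyr::mutate(.frac = .data$family_count / sum(.data$family_count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.frac >= min_allele_frac) |>
    dplyr::select("sample_id", "locus_id", "tract_len_units")
}

# novel-length statistic of tumor profiles against a support set given as a
# tibble (key_cols..., tract_len_units); returns per-(sample, locus) totals
novel_stats <- function(tumor_profiles, support, by) {
  tumor_profiles |>
    dplyr::left_join(
      dplyr::mutate(support, .in_support = TRUE),
      by = c(by, "tract_len_units")
    ) |>
    dplyr::group_by(.data$sample_id, .data$locus_id) |>
    dplyr::summarise(
      coverage_tumor = sum(.data$family_count),
      novel = sum(.data$family_count[is.na(.data$.in_support)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(statistic = .data$novel / .data$coverage_tumor)
}

finish_calls <- function(calls, tau, min_cov, mode, min_cov_ref = min_cov) {
  calls |>
    dplyr::mutate(
      no_call = .data$coverage_tumor < min_cov |
        .data$coverage_ref < min_cov_ref |
        is.na(.data$statistic),
      statistic = ifelse(.data$no_call, NA_real_, .data$statistic),
      unstable = !.data$no_call & .data$statistic >= tau &
        dplyr::coalesce(.data$pass_extra, TRUE),
      mode = mode
    ) |>
    dplyr::select("sample_id", "locus_id", "statistic", "unstable",
                  "no_call", "coverage_tumor", "coverage_ref", "mode") |>
    dplyr::arrange(.data$sample_id, .data$locus_id)
}

#' Call instability at one locus from a matched tumor/normal pair
#'
#' The statistic is the fraction of tumor consensus families whose tract
#' length lies outside the matched normal's allele support
#' ([normal_support()]). The locus is unstable when the statistic reaches
#' `tau` and both samples have at least `min_cov` families; otherwise, low
#' coverage on either side yields a no-call (never an instability call).
#'
#' @param tumor_profile,normal_profile Profile tibble rows for the same locus
#'   in the tumor and its matched normal (columns `sample_id`, `locus_id`,
#'   `tract_len_units`, `family_count`).
#' @param tau Novel-fraction threshold for instability.
#' @param min_cov Minimum consensus families per sample.
#' @param min_allele_frac Passed to [normal_support()].
#' @return One-row call tibble: `sample_id`, `locus_id`, `statistic`,
#'   `unstable`, `no_call`, `coverage_tumor`, `coverage_ref`, `mode`.
#' @export
call_paired <- function(tumor_profile, normal_profile, tau = 0.10,
                        min_cov = 20L, min_allele_frac = 0.05) {
  lt <- unique(tumor_profile$locus_id)
  ln <- unique(normal_profile$locus_id)
  if (length(lt) != 1L || length(ln) != 1L || lt != ln) {
    abort("tumor and normal profiles must refer to one common locus")
  }
  cov_t <- sum(tumor_profile$family_count)
  cov_n <- sum(normal_profile$family_count)
  sid <- tumor_profile$sample_id[1]
  if (cov_t < min_cov || cov_n < min_cov) {
    return(tibble::tibble(sample_id = sid, locus_id = lt,
                          statistic = NA_real_, unstable = FALSE,
                          no_call = TRUE, coverage_tumor = cov_t,
                          coverage_ref = cov_n, mode = "paired"))
  }
  supp <- normal_support(normal_profile, min_allele_frac)
  stat <- sum(tumor_profile$family_count[
    !tumor_profile$tract_len_units %in% supp
  ]) / cov_t
  tibble::tibble(sample_id = sid, locus_id = lt, statistic = stat,
                 unstable = stat >= tau, no_call = FALSE,
                 coverage_tumor = cov_t, coverage_ref = cov_n,
                 mode = "paired")
}

#' Paired tumor-vs-normal instability calls across a cohort
#'
#' Vectorized [call_paired()] over every tumor that has a matched normal in
#' the sample sheet. Loci covered in neither member of a pair, or listed in
#' `loci` but absent from a profile, are emitted as explicit no-calls so
#' downstream classification always sees a complete grid.
#'
#' @param profiles Long profile tibble from [collapse_to_profile()]
#'   (tumors and normals together).
#' @param samples Sample sheet tibble: `sample_id`, `patient_id`, `tissue`.
#' @param loci Locus ids to call; default: all loci present in `profiles`.
#' @param tau,min_cov,min_allele_frac As in [call_paired()].
#' @return Call tibble, one row per (tumor sample, locus).
#' @export
call_paired_cohort <- function(profiles, samples, loci = NULL, tau = 0.10,
                               min_cov = 20L, min_allele_frac = 0.05) {
  if (is.null(loci)) loci <- sort(unique(profiles$locus_id))
  pairs <- samples |>
    dplyr::filter(.data$tissue %in% c("tumor", "normal")) |>
    dplyr::distinct(.data$sample_id, .data$patient_id, .data$tissue) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "sample_id") |>
    dplyr::filter(!is.na(.data$tumor) & !is.na(.data$normal))
  grid <- tidyr::expand_grid(pairs, locus_id = loci)

  totals <- profiles |>
    dplyr::group_by(.data$sample_id, .data$locus_id) |>
    dplyr::summarise(n_fam = sum(.data$family_count), .groups = "drop")

  nsupp <- support_table(
    dplyr::semi_join(profiles,
                     tibble::tibble(sample_id = pairs$normal),
                     by = "sample_id"),
    min_allele_frac
  ) |>
    dplyr::rename(normal = "sample_id")

  tprof <- profiles |>
    dplyr::inner_join(dplyr::select(pairs, sample_id = "tumor", "normal"),
                      by = "sample_id")
  stats <- tprof |>
    dplyr::left_join(dplyr::mutate(nsupp, .in_support = TRUE),
                     by = c("normal", "locus_id", "tract_len_units")) |>
    dplyr::group_by(.data$sample_id, .data$locus_id) |>
    dplyr::summarise(
      novel = sum(.data$family_count[is.na(.data$.in_support)]),
      .groups = "drop"
    )

  grid |>
    dplyr::left_join(dplyr::rename(totals, coverage_tumor = "n_fam"),
                     by = c(tumor = "sample_id", "locus_id")) |>
    dplyr::left_join(dplyr::rename(totals, coverage_ref = "n_fam"),
                     by = c(normal = "sample_id", "locus_id")) |>
    dplyr::left_join(stats, by = c(tumor = "sample_id", "locus_id")) |>
    dplyr::mutate(
      sample_id = .data$tumor,
      coverage_tumor = dplyr::coalesce(.data$coverage_tumor, 0L),
      coverage_ref = dplyr::coalesce(.data$coverage_ref, 0L),
      statistic = .data$novel / .data$coverage_tumor,
      pass_extra = TRUE
    ) |>
    finish_calls(tau, min_cov, "paired")
}

#' Build a panel-of-normals baseline per locus
#'
#' Pools the allele supports of all normal samples per locus
#' (`pooled_support` = union of each normal's [normal_support()]), then
#' scores every normal's own novel fraction against that pooled support
#' (leave-one-in: a normal's support is part of the pool it is scored
#' against) and records the mean and SD across normals. The baseline lets
#' unmatched tumors be called via [call_unpaired()].
#'
#' @param normal_profiles Long profile tibble restricted to normal samples.
#' @param min_allele_frac Passed to [normal_support()].
#' @return Baseline tibble: `locus_id`, `pooled_support` (list column of
#'   integer vectors), `n_normals`, `mean_novel_frac`, `sd_novel_frac`
#'   (0 when only one normal covers the locus).
#' @export
build_baseline <- function(normal_profiles, min_allele_frac = 0.05) {
  if (nrow(normal_profiles) == 0L) {
    abort("`normal_profiles` must contain at least one normal sample")
  }
  supp <- support_table(normal_profiles, min_allele_frac)
  pooled <- supp |>
    dplyr::distinct(.data$locus_id, .data$tract_len_units) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      pooled_support = list(sort(.data$tract_len_units)),
      .groups = "drop"
    )
  per_normal <- novel_stats(
    normal_profiles,
    dplyr::distinct(supp, .data$locus_id, .data$tract_len_units),
    by = "locus_id"
  )
  stats <- per_normal |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_normals = dplyr::n(),
      mean_novel_frac = mean(.data$statistic),
      sd_novel_frac = ifelse(dplyr::n() > 1L, sd(.data$statistic), 0),
      .groups = "drop"
    )
  dplyr::inner_join(pooled, stats, by = "locus_id") |>
    dplyr::arrange(.data$locus_id)
}

#' Call instability at one locus for an unmatched tumor
#'
#' Baseline mode for tumors without a matched normal: the statistic is the
#' tumor's novel-length family fraction against the pooled normal support,
#' and instability additionally requires the statistic to exceed the
#' baseline's mean novel fraction by `z_min` baseline standard deviations
#' (with an SD floor, so a noiseless baseline cannot produce infinite
#' z-scores).
#'
#' @param tumor_profile Profile rows for one (tumor sample, locus).
#' @param baseline Baseline tibble from [build_baseline()].
#' @param z_min Minimum z-score against the baseline.
#' @param tau Novel-fraction threshold.
#' @param min_cov Minimum tumor consensus families.
#' @param sd_floor Lower bound on the baseline SD used in the z-score.
#' @return One-row call tibble (`mode = "baseline"`); a missing baseline for
#'   the locus yields a no-call.
#' @export
call_unpaired <- function(tumor_profile, baseline, z_min = 3.0, tau = 0.10,
                          min_cov = 20L, sd_floor = 0.01) {
  lt <- unique(tumor_profile$locus_id)
  if (length(lt) != 1L) abort("`tumor_profile` must cover exactly one locus")
  calls <- call_baseline_cohort(tumor_profile, baseline, loci = lt,
                                z_min = z_min, tau = tau, min_cov = min_cov,
                                sd_floor = sd_floor)
  calls
}

#' Baseline-mode instability calls for a set of tumors
#'
#' Vectorized [call_unpaired()] across tumors and loci. Loci without a
#' baseline entry, or with tumor coverage below `min_cov`, are no-calls.
#'
#' @param tumor_profiles Long profile tibble of tumor samples.
#' @param baseline Baseline tibble from [build_baseline()].
#' @param loci Locus ids to call; default: union of profile and baseline loci.
#' @param z_min,tau,min_cov,sd_floor As in [call_unpaired()].
#' @return Call tibble, one row per (tumor sample, locus).
#' @export
call_baseline_cohort <- function(tumor_profiles, baseline, loci = NULL,
                                 z_min = 3.0, tau = 0.10, min_cov = 20L,
                                 sd_floor = 0.01) {
  if (is.null(loci)) {
    loci <- sort(union(unique(tumor_profiles$locus_id), baseline$locus_id))
  }
  support <- baseline |>
    dplyr::select("locus_id", "pooled_support") |>
    tidyr::unnest(cols = "pooled_support") |>
    dplyr::rename(tract_len_units = "pooled_support")

  stats <- novel_stats(
    dplyr::semi_join(tumor_profiles, tibble::tibble(locus_id = loci),
                     by = "locus_id"),
    support, by = "locus_id"
  )
  grid <- tidyr::expand_grid(
    sample_id = sort(unique(tumor_profiles$sample_id)),
    locus_id = loci
  )
  grid |>
    dplyr::left_join(stats, by = c("sample_id", "locus_id")) |>
    dplyr::left_join(
      dplyr::select(baseline, "locus_id", "n_normals",
                    "mean_novel_frac", "sd_novel_frac"),
      by = "locus_id"
    ) |>
    dplyr::mutate(
      coverage_tumor = dplyr::coalesce(.data$coverage_tumor, 0L),
      has_baseline = !is.na(.data$n_normals),
      # reference "coverage" in baseline mode = normals backing the baseline;
      # a locus with no baseline entry is never callable
      coverage_ref = dplyr::coalesce(.data$n_normals, 0L),
      statistic = ifelse(.data$has_baseline, .data$statistic, NA_real_),
      pass_extra = .data$has_baseline &
        (.data$statistic - .data$mean_novel_frac) >=
          z_min * pmax(.data$sd_novel_frac, sd_floor)
    ) |>
    finish_calls(tau, min_cov, "baseline", min_cov_ref = 1L)
}
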