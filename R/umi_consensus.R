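#' Collapse UMI read families to consensus repeat-length profiles
#'
#' Reads sharing a (sample, locus, UMI) triplet form one family — one input
#' molecule. Each family contributes a single consensus tract length, the
#' strict-majority read length (> half the reads agree). Families with no
#' strict majority are dropped and tallied, as are families smaller than
#' `min_family_size`. This is the error-suppression step of UMI sequencing:
#' stutter hits individual reads, so the family majority recovers the
#' molecule's true length whenever fewer than half its reads slipped.
#'
#' `min_family_size = 1` (the default) lets the pipeline degrade gracefully
#' to non-UMI data — single-read families pass through unchanged; 3 is a
#' sensible choice for real UMI libraries.
#'
#' @param observations Tibble of UMI observations: `sample_id`, `locus_id`,
#'   `umi`, `tract_len_units` (positive integers).
#' @param min_family_size Families with fewer reads are discarded.
#' @return A long profile tibble — `sample_id`, `locus_id`,
#'   `tract_len_units`, `family_count` — containing only (sample, locus)
#'   pairs with at least one surviving family. A per-sample QC tibble
#'   (`families_in`, `families_below_min`, `families_tied`) is attached as
#'   attribute `"qc"`; see [collapse_qc()].
#' @examples
#' obs <- tibble::tibble(
#'   sample_id = "S1", locus_id = "L1",
#'   umi = c("a", "a", "a", "b", "b"),
#'   tract_len_units = c(10L, 10L, 11L, 10L, 11L)
#' )
#' collapse_to_profile(obs)  # family a -> 10; family b tied, dropped
#' @export
collapse_to_profile <- function(observations, min_family_size = 1L) {
  req <- c("sample_id", "locus_id", "umi", "tract_len_units")
  if (!all(req %in% names(observations))) {
    abort(paste0("`observations` must have columns: ",
                 paste(req, collapse = ", ")))
  }
  if (min_family_size < 1L) abort("`min_family_size` must be >= 1")
  if (nrow(observations) == 0L) {
    out <- tibble::tibble(sample_id = character(), locus_id = character(),
                          tract_len_units = integer(),
                          family_count = integer())
    attr(out, "qc") <- tibble::tibble(sample_id = character(),
                                      families_in = integer(),
                                      families_below_min = integer(),
                                      families_tied = integer())
    return(out)
  }
  if (any(is.na(observations$tract_len_units)) ||
      any(observations$tract_len_units < 1L)) {
    abort("`tract_len_units` must be positive integers")
  }
  if (any(!nzchar(observations$umi))) abort("`umi` must be non-empty")

  DT <- data.table::as.data.table(
    observations[, c("sample_id", "locus_id", "umi", "tract_len_units")]
  )
  cnt <- DT[, list(n = .N),
            by = c("sample_id", "locus_id", "umi", "tract_len_units")]
  # leading row per family after this ordering = (max read count, then
  # smallest length among argmax) -> candidate consensus
  data.table::setorderv(cnt,
                        c("sample_id", "locus_id", "umi", "n", "tract_len_units"),
                        order = c(1L, 1L, 1L, -1L, 1L))
  top <- unique(cnt, by = c("sample_id", "locus_id", "umi"))
  data.table::setnames(top, c("tract_len_units", "n"), c("cons", "nmax"))
  sizes <- cnt[, list(size = sum(n)), by = c("sample_id", "locus_id", "umi")]
  fam <- top[sizes, on = c("sample_id", "locus_id", "umi")]
  # strict majority <=> 2 * nmax > size (a tie at nmax forces 2 * nmax <= size)
  fam[, `:=`(majority = 2L * nmax > size, big = size >= min_family_size)]
  qc <- fam[, list(
    families_in = .N,
    families_below_min = sum(!big),
    families_tied = sum(big & !majority)
  ), by = "sample_id"]
  keep <- fam[fam$big & fam$majority]
  prof <- keep[, list(family_count = .N),
               by = c("sample_id", "locus_id", "cons")]
  data.table::setnames(prof, "cons", "tract_len_units")
  data.table::setorderv(prof, c("sample_id", "locus_id", "tract_len_units"))
  out <- tibble::as_tibble(prof)
  out$tract_len_units <- as.integer(out$tract_len_units)
  out$family_count <- as.integer(out$family_count)
  attr(out, "qc") <- tibble::as_tibble(qc)
  out
}

#' Extract the per-sample QC tally from a collapsed profile table
#'
#' @param profiles Output of [collapse_to_profile()].
#' @return Tibble with `sample_id`, `families_in`, `families_below_min`,
#'   `families_tied`.
#' @export
collapse_qc <- function(profiles) {
  qc <- attr(profiles, "qc")
  if (is.null(qc)) abort("`profiles` carries no QC attribute")
  qc
}
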