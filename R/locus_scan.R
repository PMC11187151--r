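#' Canonicalize a microsatellite repeat unit
#'
#' Reduces a repeat unit to its canonical form: the lexicographically smallest
#' rotation. Units that are themselves a whole-number repetition of a shorter
#' unit (e.g. `"AA"`, `"ACAC"`) are not primitive and are rejected, so that
#' every repeat tract has exactly one canonical description.
#'
#' @param unit Uppercase DNA string over `{A,C,G,T}`.
#' @return The canonical (smallest-rotation) unit as a length-1 character
#'   vector, or `NA_character_` if the unit is not primitive.
#' @examples
#' canonical_unit("TA")   # "AT"
#' canonical_unit("ACG")  # "ACG"
#' canonical_unit("AA")   # NA: not primitive
#' @export
canonical_unit <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L, nzchar(unit))
  if (grepl("[^ACGT]", unit)) {
    abort(paste0("unit contains non-ACGT characters: ", unit))
  }
  if (!is_primitive_unit(unit)) {
    return(NA_character_)
  }
  n <- nchar(unit)
  if (n == 1L) return(unit)
  doubled <- paste0(unit, unit)
  rotations <- vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), "")
  min(rotations)
}

# primitive <=> no proper divisor length d of n has unit == rep(prefix_d)
is_primitive_unit <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), n %/% d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Scan reference sequences for candidate microsatellite loci
#'
#' Finds every maximal tandem-repeat tract whose primitive unit is
#' `min_unit`-`max_unit` bp long and repeats a whole number of times between
#' `min_copies` and `max_copies` (inclusive). These bounds default to the
#' 1-5 bp unit / 7-13 copy window typical of clinically informative
#' microsatellites. Tracts exceeding `max_copies` whole copies are excluded
#' entirely rather than truncated (set `enforce_upper = FALSE` to keep them).
#'
#' Copies are counted as whole units only: a trailing partial unit is excluded
#' from the reported tract. Only the forward strand is scanned; the canonical
#' unit rotation makes reporting deterministic, and a tract's reverse
#' complement is the same genomic feature. Any non-ACGT character (e.g. `N`
#' masking) terminates a tract.
#'
#' @param sequences Named character vector of DNA sequences (uppercase), or a
#'   `Biostrings::DNAStringSet`.
#' @param min_unit,max_unit Repeat-unit length bounds in bp.
#' @param min_copies,max_copies Whole-copy count bounds.
#' @param enforce_upper If `FALSE`, tracts with more than `max_copies` copies
#'   are reported instead of excluded.
#' @return A tibble with one row per locus: `locus_id`, `chrom`, `start`
#'   (0-based), `end` (exclusive), `unit` (canonical rotation), `unit_len`,
#'   `copies`, `gene_label` (`NA`), sorted by (`chrom`, `start`).
#' @examples
#' scan_reference(c(chr1 = "CCAAAAAAACC"))
#' @export
scan_reference <- function(sequences, min_unit = 1L, max_unit = 5L,
                           min_copies = 7L, max_copies = 13L,
                           enforce_upper = TRUE) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0L) abort("`sequences` must be non-empty")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("`sequences` must be named (one name per record)")
  }
  stopifnot(min_unit >= 1L, min_unit <= max_unit,
            min_copies >= 1L, min_copies <= max_copies)

  out <- purrr::imap(sequences, function(seq, chrom) {
    scan_one_sequence(toupper(seq), chrom, min_unit, max_unit,
                      min_copies, max_copies, enforce_upper)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(empty_catalog())
  }
  res <- dplyr::arrange(res, .data$chrom, .data$start, .data$unit_len)
  res$locus_id <- paste0(res$chrom, ":", res$start, "-", res$end, ":", res$unit)
  dplyr::select(res, "locus_id", "chrom", "start", "end",
                "unit", "unit_len", "copies", "gene_label")
}

empty_catalog <- function() {
  tibble::tibble(
    locus_id = character(), chrom = character(),
    start = integer(), end = integer(),
    unit = character(), unit_len = integer(), copies = integer(),
    gene_label = character()
  )
}

# Maximal period-u runs via vectorized self-comparison at offset u:
# a maximal TRUE-run of length m in (s[i] == s[i+u]) starting at p spans a
# region of length m + u with period u; whole copies = (m + u) %/% u.
scan_one_sequence <- function(seq, chrom, min_unit, max_unit,
                              min_copies, max_copies, enforce_upper) {
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- list()
  for (u in seq.int(min_unit, max_unit)) {
    if (L < u * min_copies) next
    eq <- chars[seq_len(L - u)] == chars[seq.int(u + 1L, L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + u >= u * min_copies)
    if (!any(keep)) next
    for (k in which(keep)) {
      p <- starts[k]                      # 1-based start of the run region
      region_len <- r$lengths[k] + u
      copies <- region_len %/% u
      if (copies < min_copies) next
      if (enforce_upper && copies > max_copies) next
      unit_raw <- substr(seq, p, p + u - 1L)
      if (grepl("[^ACGT]", unit_raw)) next
      if (!is_primitive_unit(unit_raw)) next
      hits[[length(hits) + 1L]] <- list(
        chrom = chrom,
        start = p - 1L,                   # 0-based
        end = p - 1L + copies * u,
        unit = canonical_unit(unit_raw),
        unit_len = u,
        copies = copies
      )
    }
  }
  if (length(hits) == 0L) return(NULL)
  res <- dplyr::bind_rows(hits)
  res$gene_label <- NA_character_
  res
}

#' Read reference sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_ref_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  # minimal fallback parser (plain text, uncompressed)
  lines <- readLines(path)
  idx <- cumsum(startsWith(lines, ">"))
  headers <- sub("^>", "", sub("\\s.*$", "", lines[startsWith(lines, ">")]))
  body <- split(lines[!startsWith(lines, ">")], idx[!startsWith(lines, ">")])
  out <- toupper(vapply(body, paste0, "", collapse = ""))
  names(out) <- headers
  out
}

#' Write a locus catalog as BED6 plus a TSV sidecar
#'
#' BED columns: chrom, start, end, locus_id, copies (score), strand (`+`),
#' 0-based half-open. The sidecar carries `locus_id`, `unit`, `unit_len`,
#' `copies`, `gene_label`.
#'
#' @param catalog Tibble from [scan_reference()].
#' @param bed_path,tsv_path Output paths.
#' @return `catalog`, invisibly.
#' @export
write_locus_catalog <- function(catalog, bed_path, tsv_path) {
  bed <- dplyr::transmute(catalog, .data$chrom, .data$start, .data$end,
                          .data$locus_id, score = .data$copies, strand = "+")
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  readr::write_tsv(
    dplyr::select(catalog, "locus_id", "unit", "unit_len", "copies", "gene_label"),
    tsv_path
  )
  invisible(catalog)
}

#' Read a locus catalog written by [write_locus_catalog()]
#'
#' @param bed_path,tsv_path Paths written by [write_locus_catalog()].
#' @return A catalog tibble in [scan_reference()] layout.
#' @export
read_locus_catalog <- function(bed_path, tsv_path) {
  bed <- readr::read_tsv(
    bed_path,
    col_names = c("chrom", "start", "end", "locus_id", "score", "strand"),
    col_types = "ciicic"
  )
  side <- readr::read_tsv(tsv_path, col_types = "cciic")
  dplyr::inner_join(bed, side, by = "locus_id") |>
    dplyr::transmute(.data$locus_id, .data$chrom, .data$start, .data$end,
                     .data$unit, .data$unit_len, .data$copies, .data$gene_label)
}
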