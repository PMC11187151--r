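#' Assemble a samples-by-loci call matrix
#'
#' Pivots a long call tibble into the boolean substrate of panel selection:
#' an `unstable` matrix and a `no_call` mask over tumor samples (rows) and
#' loci (columns), annotated with per-sample MMR labels and cohort
#' membership. Normals are excluded. Missing (sample, locus) combinations
#' are treated as no-calls.
#'
#' @param calls Call tibble from [call_paired_cohort()] or
#'   [call_baseline_cohort()].
#' @param samples Sample sheet tibble (`sample_id`, `tissue`, `mmr_status`,
#'   `cohort`).
#' @return A `call_matrix` object.
#' @export
build_call_matrix <- function(calls, samples) {
  tum <- dplyr::filter(samples, .data$tissue == "tumor")
  calls <- dplyr::semi_join(calls, tum, by = "sample_id")
  sample_ids <- sort(unique(tum$sample_id[tum$sample_id %in% calls$sample_id]))
  locus_ids <- sort(unique(calls$locus_id))
  U <- matrix(FALSE, length(sample_ids), length(locus_ids),
              dimnames = list(sample_ids, locus_ids))
  NC <- matrix(TRUE, length(sample_ids), length(locus_ids),
               dimnames = list(sample_ids, locus_ids))
  idx <- cbind(match(calls$sample_id, sample_ids),
               match(calls$locus_id, locus_ids))
  U[idx] <- calls$unstable
  NC[idx] <- calls$no_call
  meta <- tum[match(sample_ids, tum$sample_id), ]
  structure(
    list(
      unstable = U,
      no_call = NC,
      labels = stats::setNames(meta$mmr_status, sample_ids),
      cohort = stats::setNames(meta$cohort, sample_ids),
      sample_ids = sample_ids,
      locus_ids = locus_ids
    ),
    class = "call_matrix"
  )
}

#' @export
print.call_matrix <- function(x, ...) {
  cat("<call_matrix> ", length(x$sample_ids), " tumors x ",
      length(x$locus_ids), " loci\n", sep = "")
  cat("  labels: ", paste(names(table(x$labels)), table(x$labels),
                          sep = "=", collapse = ", "), "\n", sep = "")
  cat("  cohort: ", paste(names(table(x$cohort)), table(x$cohort),
                          sep = "=", collapse = ", "), "\n", sep = "")
  cat("  no-call rate: ", sprintf("%.3f", mean(x$no_call)), "\n", sep = "")
  invisible(x)
}

cm_rows <- function(cm, cohort = NULL) {
  if (is.null(cohort)) return(cm$sample_ids)
  cm$sample_ids[cm$cohort[cm$sample_ids] %in% cohort]
}

#' Filter out germline-polymorphic loci
#'
#' A locus whose modal consensus length differs across more than
#' `max_polymorphic_frac` of normal samples is germline-polymorphic
#' (population allele-length variation, not somatic instability) and is
#' removed before marker selection — such loci would otherwise light up in
#' baseline mode purely from germline variation. The reference modal length
#' is the majority modal length across normals; per-sample modal ties break
#' toward the shorter length.
#'
#' @param normal_profiles Long profile tibble of normal samples.
#' @param max_polymorphic_frac Maximum tolerated fraction of discordant
#'   normals (boundary inclusive: a locus is kept at exactly this fraction).
#' @return Character vector of retained locus ids (sorted).
#' @export
polymorphism_filter <- function(normal_profiles, max_polymorphic_frac = 0.05) {
  if (nrow(normal_profiles) == 0L) {
    warn("no normal profiles; polymorphism filter skipped")
    return(character(0))
  }
  modal <- normal_profiles |>
    dplyr::group_by(.data$sample_id, .data$locus_id) |>
    dplyr::slice_max(.data$family_count, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.data$tract_len_units, n = 1) |>
    dplyr::ungroup()
  modal |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_discordant = dplyr::n() - max(table(.data$tract_len_units)),
      n_normals = dplyr::n(),
      .groups = "drop"
    ) |>
    # integer comparison avoids a floating-point boundary at the threshold
    dplyr::filter(.data$n_discordant <= max_polymorphic_frac * .data$n_normals) |>
    dplyr::pull("locus_id") |>
    sort()
}

#' Per-locus instability frequencies by MMR class
#'
#' No-call entries are excluded from denominators throughout.
#'
#' @param cm A `call_matrix`.
#' @param loci Locus ids (default: all in `cm`).
#' @param cohort Restrict to these cohort values (default: all rows).
#' @return Tibble: `locus_id`, `freq_dmmr`, `freq_pmmr`, `freq_all`,
#'   `n_dmmr`, `n_pmmr` (evaluable counts).
#' @export
locus_frequencies <- function(cm, loci = NULL, cohort = NULL) {
  if (is.null(loci)) loci <- cm$locus_ids
  rows <- cm_rows(cm, cohort)
  U <- cm$unstable[rows, loci, drop = FALSE]
  NC <- cm$no_call[rows, loci, drop = FALSE]
  lab <- cm$labels[rows]
  freq_in <- function(mask) {
    ev <- colSums((!NC)[mask, , drop = FALSE])
    un <- colSums((U & !NC)[mask, , drop = FALSE])
    list(freq = ifelse(ev > 0, un / ev, NA_real_), n = ev)
  }
  fd <- freq_in(lab == "dMMR")
  fp <- freq_in(lab == "pMMR")
  fa <- freq_in(rep(TRUE, length(lab)))
  tibble::tibble(
    locus_id = loci,
    freq_dmmr = unname(fd$freq), freq_pmmr = unname(fp$freq),
    freq_all = unname(fa$freq),
    n_dmmr = unname(fd$n), n_pmmr = unname(fp$n)
  )
}

#' Retain loci enriched for instability in dMMR tumors
#'
#' Keeps loci whose training-tumor instability frequency is at least
#' `min_dmmr_freq` among dMMR tumors and at most `max_pmmr_freq` among pMMR
#' tumors — the "characteristic of mismatch-repair deficiency" stage of the
#' selection cascade.
#'
#' @param cm A `call_matrix`.
#' @param min_dmmr_freq,max_pmmr_freq Frequency bounds (inclusive).
#' @param loci Candidate pool (default: all loci in `cm`).
#' @param cohort Rows to use (default `"train"`).
#' @return Character vector of retained locus ids (sorted).
#' @export
dmmr_enrichment_filter <- function(cm, min_dmmr_freq = 0.30,
                                   max_pmmr_freq = 0.05, loci = NULL,
                                   cohort = "train") {
  rows <- cm_rows(cm, cohort)
  lab <- cm$labels[rows]
  if (length(unique(lab)) < 2L) {
    abort("both dMMR and pMMR tumors are required")
  }
  fr <- locus_frequencies(cm, loci, cohort)
  fr |>
    dplyr::filter(!is.na(.data$freq_dmmr), !is.na(.data$freq_pmmr),
                  .data$freq_dmmr >= min_dmmr_freq,
                  .data$freq_pmmr <= max_pmmr_freq) |>
    dplyr::pull("locus_id") |>
    sort()
}

#' Cluster loci by their instability-frequency profiles
#'
#' Two-stage clustering mirroring the selection workflow: hierarchical
#' agglomeration (Ward linkage on Euclidean distances) cut into `n_clusters`
#' groups, whose centroids then seed K-means with `k = n_clusters`. The
#' K-means assignment is returned. Features are the per-locus instability
#' frequencies in dMMR tumors, in pMMR tumors, and overall (frequency
#' features rather than raw per-sample indicator vectors, so clusters do not
#' depend on sample ordering or cohort size; set `features` to use your own
#' matrix). Features are left on their common frequency scale by default:
#' column standardization (`standardize = TRUE`) rescales near-constant
#' columns — typically the pMMR frequency, where a single discordant tumor
#' moves a locus by the whole column SD — and lets sampling noise dominate
#' the distances.
#'
#' @param cm A `call_matrix`, or `NULL` when `features` is given.
#' @param n_clusters Number of clusters.
#' @param seed Integer seed (the procedure is deterministic given inputs and
#'   seed).
#' @param loci Loci to cluster (default: all in `cm`).
#' @param cohort Rows used for frequency features (default `"train"`).
#' @param features Optional numeric matrix (rows = loci, rownames = locus
#'   ids) overriding the built-in frequency features.
#' @param standardize Standardize feature columns before clustering.
#' @return Tibble: `locus_id`, `cluster` (integer in `1:n_clusters`).
#' @export
cluster_loci <- function(cm = NULL, n_clusters = 6L, seed = 1L, loci = NULL,
                         cohort = "train", features = NULL,
                         standardize = FALSE) {
  if (is.null(features)) {
    fr <- locus_frequencies(cm, loci, cohort)
    features <- as.matrix(fr[, c("freq_dmmr", "freq_pmmr", "freq_all")])
    rownames(features) <- fr$locus_id
    features[is.na(features)] <- 0
  }
  if (nrow(features) < n_clusters) {
    abort("fewer loci than clusters")
  }
  if (standardize) {
    X <- scale(features)
    X[, attr(X, "scaled:scale") == 0 | is.na(attr(X, "scaled:scale"))] <- 0
    X[is.na(X)] <- 0
  } else {
    X <- features
  }
  hc <- hclust(dist(X), method = "ward.D2")
  h_assign <- cutree(hc, k = n_clusters)
  centroids <- do.call(rbind, lapply(seq_len(n_clusters), function(g) {
    colMeans(X[h_assign == g, , drop = FALSE])
  }))
  set.seed(seed)
  assign <- if (anyDuplicated(round(centroids, 10))) {
    # K-means cannot start from coincident centers; in that degenerate case
    # the hierarchical cut already is the fixed point we want
    h_assign
  } else {
    km <- kmeans(X, centers = centroids, iter.max = 100L)
    km$cluster
  }
  tibble::tibble(locus_id = rownames(X), cluster = as.integer(assign))
}

#' Pick the cluster(s) most differential between dMMR and pMMR
#'
#' Scores every cluster by the mean over its loci of
#' `freq_dmmr - freq_pmmr` and returns the loci of the top-scoring cluster,
#' plus any cluster whose score is within `tol` of the maximum.
#'
#' @param assignments Tibble from [cluster_loci()].
#' @param cm A `call_matrix`.
#' @param tol Tie tolerance on the cluster score.
#' @param cohort Rows used for frequencies (default `"train"`).
#' @return Character vector of candidate locus ids (sorted).
#' @export
select_differential_cluster <- function(assignments, cm, tol = 0.05,
                                        cohort = "train") {
  if (nrow(assignments) == 0L) abort("`assignments` is empty")
  fr <- locus_frequencies(cm, assignments$locus_id, cohort)
  gaps <- assignments |>
    dplyr::inner_join(fr, by = "locus_id") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      gap = mean(.data$freq_dmmr - .data$freq_pmmr, na.rm = TRUE),
      .groups = "drop"
    )
  keep <- gaps$cluster[gaps$gap >= max(gaps$gap) - tol]
  sort(assignments$locus_id[assignments$cluster %in% keep])
}

#' Per-locus diagnostic metrics against MMR labels
#'
#' Sensitivity = unstable dMMR tumors / evaluable dMMR tumors; specificity =
#' stable pMMR tumors / evaluable pMMR tumors; no-calls are excluded from
#' denominators. A class with zero evaluable tumors yields `NA` for its
#' metric.
#'
#' @param cm A `call_matrix`.
#' @param loci Locus ids (default: all).
#' @param cohort Rows to use (default: all).
#' @return Tibble: `locus_id`, `sensitivity`, `specificity` (fractions in
#'   `[0, 1]`), `n_dmmr`, `n_pmmr`.
#' @export
per_locus_metrics <- function(cm, loci = NULL, cohort = NULL) {
  fr <- locus_frequencies(cm, loci, cohort)
  dplyr::transmute(fr, .data$locus_id,
                   sensitivity = .data$freq_dmmr,
                   specificity = 1 - .data$freq_pmmr,
                   n_dmmr = .data$n_dmmr, n_pmmr = .data$n_pmmr)
}

#' Run the full locus-selection cascade
#'
#' Convenience wrapper chaining the stages: germline-polymorphism filter on
#' normals, dMMR-enrichment filter, optional restriction to mononucleotide
#' loci, hierarchical + K-means clustering, and differential-cluster
#' selection. Returns the candidate set with the intermediate stages
#' recorded.
#'
#' @param cm A `call_matrix` (training tumors).
#' @param normal_profiles Long profile tibble of normal samples (for the
#'   polymorphism filter); `NULL` skips that stage with a warning.
#' @param catalog Locus catalog tibble (for the mononucleotide restriction);
#'   `NULL` skips it.
#' @param mononucleotide_only Keep only unit-length-1 loci as candidates.
#' @param max_polymorphic_frac,min_dmmr_freq,max_pmmr_freq,n_clusters,tol
#'   Stage parameters; see the individual stage functions.
#' @param seed Clustering seed.
#' @return List with `candidates` (character vector) and `stages` (named
#'   list of the retained-locus vectors after each stage) and `assignments`
#'   (clustering tibble).
#' @export
select_candidate_loci <- function(cm, normal_profiles = NULL, catalog = NULL,
                                  mononucleotide_only = TRUE,
                                  max_polymorphic_frac = 0.05,
                                  min_dmmr_freq = 0.30,
                                  max_pmmr_freq = 0.05,
                                  n_clusters = 6L, tol = 0.05, seed = 1L) {
  stages <- list(catalog = cm$locus_ids)
  pool <- cm$locus_ids
  if (!is.null(normal_profiles)) {
    keep <- polymorphism_filter(normal_profiles, max_polymorphic_frac)
    pool <- intersect(pool, keep)
  } else {
    warn("no normal profiles supplied; polymorphism filter skipped")
  }
  stages$polymorphism_filtered <- pool
  pool <- dmmr_enrichment_filter(cm, min_dmmr_freq, max_pmmr_freq,
                                 loci = pool)
  stages$dmmr_filtered <- pool
  if (mononucleotide_only && !is.null(catalog)) {
    pool <- intersect(pool, catalog$locus_id[catalog$unit_len == 1L])
  }
  stages$mononucleotide <- pool
  # Clustering runs on the wider (pre-enrichment) pool: the mass of null
  # loci anchors the background, so truly dMMR-enriched loci separate as a
  # group instead of being shattered into singletons when few loci survive
  # the enrichment filter. The n_clusters-category cut is the descriptive
  # landscape (heatmap layer); the operational differential/background
  # separation is a two-group cut, since the downstream panel search
  # consumes a single candidate pool. Candidates = differential group
  # intersected with the filtered pool, keeping the cascade monotone.
  cluster_pool <- stages$polymorphism_filtered
  if (length(cluster_pool) < max(n_clusters, 2L)) {
    warn("fewer filtered loci than clusters; skipping clustering stage")
    assignments <- tibble::tibble(locus_id = pool,
                                  cluster = rep(1L, length(pool)))
    candidates <- sort(pool)
  } else {
    assignments <- cluster_loci(cm, n_clusters = n_clusters, seed = seed,
                                loci = cluster_pool)
    two_groups <- cluster_loci(cm, n_clusters = 2L, seed = seed,
                               loci = cluster_pool)
    differential <- select_differential_cluster(two_groups, cm, tol = tol)
    candidates <- sort(intersect(differential, pool))
  }
  stages$candidates <- candidates
  list(candidates = candidates, stages = stages, assignments = assignments)
}

panel_key <- function(ids) paste(sort(ids), collapse = ",")

# lexicographic panel ordering: feasibility/specificity, sensitivity,
# smaller size, then sorted locus-id string
panel_better <- function(a, b, require_full_specificity) {
  if (is.null(b)) return(TRUE)
  ka <- c(a$specificity, a$sensitivity)
  kb <- c(b$specificity, b$sensitivity)
  if (require_full_specificity) {
    fa <- as.numeric(a$specificity == 1)
    fb <- as.numeric(b$specificity == 1)
    if (fa != fb) return(fa > fb)
  }
  for (i in seq_along(ka)) {
    if (ka[i] != kb[i]) return(ka[i] > kb[i])
  }
  if (length(a$ids) != length(b$ids)) return(length(a$ids) < length(b$ids))
  panel_key(a$ids) < panel_key(b$ids)
}

#' Exhaustively optimize a loci combination under the >= m-unstable rule
#'
#' Enumerates every subset of the candidate loci with `k_min` to `k_max`
#' members, classifies each training tumor MSI-H when at least
#' `min_unstable` of the subset's loci are unstable (no-calls count as
#' stable), and scores the subset's sensitivity and specificity against the
#' dMMR labels. Returns the subset maximizing sensitivity subject to
#' specificity = 100% (when `require_full_specificity`); ties break toward
#' the smaller subset, then the lexicographically smallest sorted locus-id
#' string. If no subset attains full specificity the
#' (specificity, sensitivity)-lexicographic optimum is returned with
#' `constraint_met = FALSE`.
#'
#' @param cm A `call_matrix`.
#' @param candidates Candidate locus ids (columns of `cm`).
#' @param k_min,k_max Subset size bounds.
#' @param min_unstable MSI-H threshold (loci).
#' @param require_full_specificity Demand specificity = 100% on training
#'   tumors.
#' @param cohort Training rows (default `"train"`).
#' @param subset_budget Hard cap on the number of enumerated subsets.
#' @return An `msi_panel` object: `locus_ids` (sorted), `min_unstable`,
#'   `train_sensitivity`, `train_specificity` (fractions),
#'   `constraint_met`, `selection_log` (best subset per size), and
#'   `n_subsets`.
#' @export
optimize_panel <- function(cm, candidates, k_min = 2L, k_max = 8L,
                           min_unstable = 2L,
                           require_full_specificity = TRUE,
                           cohort = "train", subset_budget = 1e6) {
  candidates <- sort(unique(candidates))
  if (length(candidates) < k_min) {
    abort("need at least `k_min` candidate loci")
  }
  if (!all(candidates %in% cm$locus_ids)) {
    abort("all candidates must be columns of the call matrix")
  }
  k_max <- min(k_max, length(candidates))
  rows <- cm_rows(cm, cohort)
  lab <- cm$labels[rows]
  if (length(unique(lab)) < 2L) abort("both label classes required")
  U <- (cm$unstable & !cm$no_call)[rows, candidates, drop = FALSE]
  storage.mode(U) <- "integer"
  pos <- lab == "dMMR"
  neg <- lab == "pMMR"

  sizes <- seq.int(k_min, k_max)
  n_subsets <- sum(choose(length(candidates), sizes))
  if (n_subsets > subset_budget) {
    abort(sprintf("subset enumeration (%d) exceeds budget (%g)",
                  n_subsets, subset_budget))
  }

  best <- NULL
  log_rows <- list()
  for (k in sizes) {
    combs <- combn(length(candidates), k)
    best_k <- NULL
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j]
      cnt <- rowSums(U[, idx, drop = FALSE])
      hit <- cnt >= min_unstable
      cand <- list(
        ids = candidates[idx],
        sensitivity = mean(hit[pos]),
        specificity = mean(!hit[neg])
      )
      if (panel_better(cand, best_k, require_full_specificity)) best_k <- cand
      if (panel_better(cand, best, require_full_specificity)) best <- cand
    }
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      size = k,
      locus_ids = panel_key(best_k$ids),
      sensitivity = best_k$sensitivity,
      specificity = best_k$specificity
    )
  }
  structure(
    list(
      locus_ids = sort(best$ids),
      min_unstable = as.integer(min_unstable),
      train_sensitivity = best$sensitivity,
      train_specificity = best$specificity,
      constraint_met = !require_full_specificity || best$specificity == 1,
      selection_log = dplyr::bind_rows(log_rows),
      n_subsets = n_subsets
    ),
    class = "msi_panel"
  )
}

#' @export
print.msi_panel <- function(x, ...) {
  cat("<msi_panel> ", length(x$locus_ids), " loci, MSI-H at >= ",
      x$min_unstable, " unstable\n", sep = "")
  cat("  loci: ", paste(x$locus_ids, collapse = ", "), "\n", sep = "")
  cat(sprintf("  training sensitivity %.2f%%, specificity %.2f%%%s\n",
              100 * x$train_sensitivity, 100 * x$train_specificity,
              if (x$constraint_met) "" else " (specificity constraint not met)"))
  invisible(x)
}

#' @rdname optimize_panel
#' @param x An `msi_panel`.
#' @param ... Unused.
#' @method tidy msi_panel
#' @export
tidy.msi_panel <- function(x, ...) {
  x$selection_log
}

#' @rdname optimize_panel
#' @method glance msi_panel
#' @export
glance.msi_panel <- function(x, ...) {
  tibble::tibble(
    n_loci = length(x$locus_ids),
    min_unstable = x$min_unstable,
    train_sensitivity = x$train_sensitivity,
    train_specificity = x$train_specificity,
    constraint_met = x$constraint_met,
    n_subsets = x$n_subsets
  )
}

#' Write / read a panel as JSON
#'
#' @param panel An `msi_panel`.
#' @param path Output path.
#' @return `panel` (write) or an `msi_panel` (read).
#' @export
write_panel_json <- function(panel, path) {
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE, digits = NA)
  invisible(panel)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$locus_ids <- as.character(x$locus_ids)
  x$selection_log <- tibble::as_tibble(x$selection_log)
  structure(x, class = "msi_panel")
}
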