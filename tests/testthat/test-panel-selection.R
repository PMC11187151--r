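test_that("build_call_matrix pivots calls and treats gaps as no-calls", {
  calls <- tibble::tibble(
    sample_id = c("T1", "T1", "T2"),
    locus_id = c("LA", "LB", "LA"),
    statistic = c(0.5, NA, 0),
    unstable = c(TRUE, FALSE, FALSE),
    no_call = c(FALSE, TRUE, FALSE),
    coverage_tumor = 50L, coverage_ref = 50L, mode = "paired"
  )
  samples <- tibble::tibble(
    sample_id = c("T1", "T2", "N1"), patient_id = c("P1", "P2", "P1"),
    tissue = c("tumor", "tumor", "normal"),
    mmr_status = c("dMMR", "pMMR", "dMMR"), cohort = "train"
  )
  cm <- build_call_matrix(calls, samples)
  expect_equal(dim(cm$unstable), c(2L, 2L))
  expect_true(cm$unstable["T1", "LA"])
  expect_true(cm$no_call["T1", "LB"])
  expect_true(cm$no_call["T2", "LB"])   # absent combination
  expect_false("N1" %in% cm$sample_ids) # normals excluded
  expect_equal(unname(cm$labels["T2"]), "pMMR")
})

test_that("polymorphism filter drops loci with discordant modal lengths", {
  mk_norms <- function(n_discordant, n_total = 100L) {
    dplyr::bind_rows(lapply(seq_len(n_total), function(i) {
      len <- if (i <= n_discordant) 12L else 10L
      hist_to_profile(stats::setNames(50L, len), sprintf("N%03d", i), "L1")
    }))
  }
  expect_equal(polymorphism_filter(mk_norms(0L)), "L1")
  expect_equal(polymorphism_filter(mk_norms(5L)), "L1")   # boundary: 5% kept
  expect_equal(polymorphism_filter(mk_norms(10L)), character(0))
  expect_warning(out <- polymorphism_filter(tibble::tibble(
    sample_id = character(), locus_id = character(),
    tract_len_units = integer(), family_count = integer()
  )), "skipped")
  expect_equal(out, character(0))
})

test_that("polymorphism filter removes planted polymorphic loci in simulation", {
  co <- small_cohort(seed = 3, n_paired = 50, n_unmatched = 0, n_loci = 60,
                     n_informative = 4, polymorphic_frac = 0.05)
  prof <- collapse_to_profile(co$reads, min_family_size = 3L)
  normals <- dplyr::semi_join(
    prof, dplyr::filter(co$samples, tissue == "normal"), by = "sample_id"
  )
  kept <- polymorphism_filter(normals)
  poly <- co$truth$polymorphic_locus_ids
  expect_gte(mean(!(poly %in% kept)), 0.9)
})

test_that("dMMR enrichment filter applies both frequency bounds", {
  set.seed(5)
  cm <- random_call_matrix(60, sprintf("L%03d", 1:200))
  kept <- dmmr_enrichment_filter(cm, min_dmmr_freq = 0.30,
                                 max_pmmr_freq = 0.25)
  # independent recount
  lab <- cm$labels[cm$sample_ids]
  ok <- character(0)
  for (l in cm$locus_ids) {
    u <- cm$unstable[, l]
    nc <- cm$no_call[, l]
    fd <- sum(u & !nc & lab == "dMMR") / sum(!nc & lab == "dMMR")
    fp <- sum(u & !nc & lab == "pMMR") / sum(!nc & lab == "pMMR")
    if (!is.na(fd) && !is.na(fp) && fd >= 0.30 && fp <= 0.25) ok <- c(ok, l)
  }
  expect_setequal(kept, ok)

  single <- random_call_matrix(10, sprintf("L%03d", 1:5), frac_dmmr = 1)
  expect_error(dmmr_enrichment_filter(single), "both")
})

test_that("cluster_loci recovers well-separated blobs and is deterministic", {
  set.seed(9)
  blob1 <- matrix(rnorm(40 * 3, mean = 0, sd = 0.05), ncol = 3)
  blob2 <- matrix(rnorm(15 * 3, mean = 5, sd = 0.05), ncol = 3)
  X <- rbind(blob1, blob2)
  rownames(X) <- sprintf("L%03d", seq_len(nrow(X)))
  a <- cluster_loci(n_clusters = 2L, seed = 1L, features = X)
  expect_equal(length(unique(a$cluster[1:40])), 1L)
  expect_equal(length(unique(a$cluster[41:55])), 1L)
  expect_false(a$cluster[1] == a$cluster[41])

  b <- cluster_loci(n_clusters = 2L, seed = 1L, features = X)
  expect_identical(a, b)

  # identical feature vectors always share a label
  X2 <- rbind(X, X[1, , drop = FALSE])
  rownames(X2)[56] <- "L_dup"
  a2 <- cluster_loci(n_clusters = 2L, seed = 1L, features = X2)
  expect_equal(a2$cluster[a2$locus_id == "L_dup"],
               a2$cluster[a2$locus_id == "L001"])

  expect_error(cluster_loci(n_clusters = 10L, features = X[1:4, ]),
               "fewer loci")
})

test_that("differential-cluster selection follows the argmax and tie rules", {
  mk_cm <- function(freqs_dmmr, freqs_pmmr, n_each = 50L) {
    loci <- sprintf("L%02d", seq_along(freqs_dmmr))
    rows <- list()
    for (i in seq_along(loci)) {
      nd <- round(freqs_dmmr[i] * n_each)
      np <- round(freqs_pmmr[i] * n_each)
      rows[[i]] <- tibble::tibble(
        sample_id = c(sprintf("D%03d", 1:n_each), sprintf("Q%03d", 1:n_each)),
        locus_id = loci[i],
        statistic = 0,
        unstable = c(rep(TRUE, nd), rep(FALSE, n_each - nd),
                     rep(TRUE, np), rep(FALSE, n_each - np)),
        no_call = FALSE, coverage_tumor = 50L, coverage_ref = 50L,
        mode = "paired"
      )
    }
    samples <- tibble::tibble(
      sample_id = c(sprintf("D%03d", 1:n_each), sprintf("Q%03d", 1:n_each)),
      patient_id = sample_id, tissue = "tumor",
      mmr_status = rep(c("dMMR", "pMMR"), each = n_each), cohort = "train"
    )
    build_call_matrix(dplyr::bind_rows(rows), samples)
  }
  # cluster A gap 0.7, cluster B gap 0.1: argmax only
  cm <- mk_cm(c(0.7, 0.7, 0.1, 0.1), c(0, 0, 0, 0))
  asg <- tibble::tibble(locus_id = sprintf("L%02d", 1:4),
                        cluster = c(1L, 1L, 2L, 2L))
  expect_setequal(select_differential_cluster(asg, cm), c("L01", "L02"))
  # gaps 0.70 and 0.68: both within the 0.05 tolerance
  cm2 <- mk_cm(c(0.70, 0.68), c(0, 0))
  asg2 <- tibble::tibble(locus_id = c("L01", "L02"), cluster = c(1L, 2L))
  expect_setequal(select_differential_cluster(asg2, cm2), c("L01", "L02"))
})

test_that("differential-cluster selection matches a brute-force recomputation", {
  set.seed(45)
  for (i in 1:10) {
    cm <- random_call_matrix(30, sprintf("L%02d", 1:24))
    asg <- tibble::tibble(locus_id = cm$locus_ids,
                          cluster = sample(1:4, 24, replace = TRUE))
    got <- select_differential_cluster(asg, cm)
    lab <- cm$labels[cm$sample_ids]
    gap_of <- function(l) {
      u <- cm$unstable[, l]; nc <- cm$no_call[, l]
      sum(u & !nc & lab == "dMMR") / sum(!nc & lab == "dMMR") -
        sum(u & !nc & lab == "pMMR") / sum(!nc & lab == "pMMR")
    }
    gaps <- vapply(split(asg$locus_id, asg$cluster),
                   function(ls) mean(vapply(ls, gap_of, numeric(1))),
                   numeric(1))
    keep <- names(gaps)[gaps >= max(gaps) - 0.05]
    want <- sort(asg$locus_id[as.character(asg$cluster) %in% keep])
    expect_identical(got, want)
  }
})

test_that("per-locus metrics count no-calls out of denominators", {
  calls <- tibble::tibble(
    sample_id = rep(c("D1", "D2", "Q1", "Q2"), each = 1),
    locus_id = "L1",
    statistic = 0,
    unstable = c(TRUE, FALSE, FALSE, FALSE),
    no_call = c(FALSE, TRUE, FALSE, FALSE),
    coverage_tumor = 50L, coverage_ref = 50L, mode = "paired"
  )
  samples <- tibble::tibble(
    sample_id = c("D1", "D2", "Q1", "Q2"), patient_id = sample_id,
    tissue = "tumor", mmr_status = c("dMMR", "dMMR", "pMMR", "pMMR"),
    cohort = "train"
  )
  m <- per_locus_metrics(build_call_matrix(calls, samples))
  expect_equal(m$sensitivity, 1)     # 1 of 1 evaluable dMMR
  expect_equal(m$specificity, 1)     # 2 of 2 evaluable pMMR stable
  expect_equal(m$n_dmmr, 1)
  expect_equal(m$n_pmmr, 2)
})

test_that("per-locus metrics match an independent recount on random matrices", {
  set.seed(9)
  cm <- random_call_matrix(40, sprintf("L%02d", 1:30))
  m <- per_locus_metrics(cm)
  lab <- cm$labels[cm$sample_ids]
  for (i in sample(30, 10)) {
    l <- cm$locus_ids[i]
    u <- cm$unstable[, l]; nc <- cm$no_call[, l]
    expect_equal(m$sensitivity[m$locus_id == l],
                 sum(u & !nc & lab == "dMMR") / sum(!nc & lab == "dMMR"))
    expect_equal(m$specificity[m$locus_id == l],
                 1 - sum(u & !nc & lab == "pMMR") / sum(!nc & lab == "pMMR"))
  }
})

test_that("optimize_panel finds the planted perfect pair", {
  set.seed(11)
  loci <- sprintf("L%02d", 1:10)
  n <- 30L
  lab <- rep(c("dMMR", "pMMR"), each = n / 2)
  U <- matrix(runif(n * 10) < 0.25, n, 10, dimnames = list(sprintf("T%02d", 1:n), loci))
  U[, "L03"] <- lab == "dMMR"
  U[, "L07"] <- lab == "dMMR"
  U[lab == "pMMR", setdiff(loci, c("L03", "L07"))] <- FALSE # keep spec attainable
  calls <- tibble::tibble(
    sample_id = rep(rownames(U), 10),
    locus_id = rep(loci, each = n),
    statistic = 0, unstable = as.vector(U), no_call = FALSE,
    coverage_tumor = 50L, coverage_ref = 50L, mode = "paired"
  )
  samples <- tibble::tibble(sample_id = rownames(U), patient_id = rownames(U),
                            tissue = "tumor", mmr_status = lab,
                            cohort = "train")
  cm <- build_call_matrix(calls, samples)
  panel <- optimize_panel(cm, loci, k_min = 2L, k_max = 4L)
  expect_equal(panel$locus_ids, c("L03", "L07"))
  expect_equal(panel$train_sensitivity, 1)
  expect_equal(panel$train_specificity, 1)
  expect_true(panel$constraint_met)
})

test_that("optimize_panel matches the independent exhaustive oracle", {
  set.seed(13)
  for (i in 1:8) {
    n_loci <- sample(8:13, 1)
    n_tum <- sample(20:40, 1)
    cm <- random_call_matrix(n_tum, sprintf("L%02d", seq_len(n_loci)),
                             p_unstable = runif(1, 0.1, 0.5))
    panel <- optimize_panel(cm, cm$locus_ids, k_min = 2L, k_max = 4L)
    U <- (cm$unstable & !cm$no_call)[cm$sample_ids, , drop = FALSE]
    want <- oracle_optimize(U, cm$labels[cm$sample_ids], k_min = 2L,
                            k_max = 4L)
    expect_identical(panel$locus_ids, want$ids)
    expect_equal(panel$train_sensitivity, want$sens)
    expect_equal(panel$train_specificity, want$spec)
  }
})

test_that("optimize_panel relaxes gracefully when full specificity is impossible", {
  n <- 10L
  lab <- rep(c("dMMR", "pMMR"), each = n / 2)
  loci <- c("LA", "LB", "LC")
  U <- matrix(TRUE, n, 3, dimnames = list(sprintf("T%02d", 1:n), loci))
  calls <- tibble::tibble(
    sample_id = rep(rownames(U), 3), locus_id = rep(loci, each = n),
    statistic = 0, unstable = TRUE, no_call = FALSE,
    coverage_tumor = 50L, coverage_ref = 50L, mode = "paired"
  )
  samples <- tibble::tibble(sample_id = rownames(U), patient_id = rownames(U),
                            tissue = "tumor", mmr_status = lab, cohort = "train")
  cm <- build_call_matrix(calls, samples)
  panel <- optimize_panel(cm, loci, k_min = 2L, k_max = 3L)
  expect_false(panel$constraint_met)
  expect_equal(panel$train_sensitivity, 1)
  expect_equal(panel$train_specificity, 0)
  # tie-breaks: smallest size, lexicographically first ids
  expect_equal(panel$locus_ids, c("LA", "LB"))
})

test_that("adding a locus never lowers sensitivity nor raises specificity", {
  set.seed(17)
  for (i in 1:10) {
    cm <- random_call_matrix(30, sprintf("L%02d", 1:8))
    U <- (cm$unstable & !cm$no_call)
    lab <- cm$labels[cm$sample_ids]
    base_ids <- sample(cm$locus_ids, 3)
    extra <- sample(setdiff(cm$locus_ids, base_ids), 1)
    score <- function(ids) {
      hit <- rowSums(U[, ids, drop = FALSE]) >= 2L
      c(sens = mean(hit[lab == "dMMR"]), spec = mean(!hit[lab == "pMMR"]))
    }
    s0 <- score(base_ids)
    s1 <- score(c(base_ids, extra))
    expect_gte(s1["sens"], s0["sens"])
    expect_lte(s1["spec"], s0["spec"])
  }
})

test_that("selection cascade output is monotone and recovers planted loci", {
  co <- small_cohort(seed = 29, n_paired = 40, n_unmatched = 0, n_loci = 60,
                     n_informative = 6)
  prof <- collapse_to_profile(co$reads, min_family_size = 3L)
  calls <- call_paired_cohort(prof, co$samples, loci = co$catalog$locus_id)
  cm <- build_call_matrix(calls, co$samples)
  normals <- dplyr::semi_join(
    prof, dplyr::filter(co$samples, tissue == "normal"), by = "sample_id"
  )
  sel <- select_candidate_loci(cm, normals, co$catalog, seed = 1L)
  st <- sel$stages
  expect_true(all(st$candidates %in% st$dmmr_filtered))
  expect_true(all(st$dmmr_filtered %in% st$polymorphism_filtered))
  expect_true(all(st$polymorphism_filtered %in% st$catalog))
  expect_gte(sum(co$truth$informative_locus_ids %in% sel$candidates), 5L)
})

test_that("panels round-trip through JSON", {
  set.seed(19)
  cm <- random_call_matrix(20, sprintf("L%02d", 1:6))
  panel <- optimize_panel(cm, cm$locus_ids, k_min = 2L, k_max = 3L,
                          require_full_specificity = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_json(panel, path)
  back <- read_panel_json(path)
  expect_equal(back$locus_ids, panel$locus_ids)
  expect_equal(back$min_unstable, panel$min_unstable)
  expect_equal(back$train_sensitivity, panel$train_sensitivity)
  expect_equal(tibble::as_tibble(back$selection_log), panel$selection_log)
})
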