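## Synthetic peak_call factory (bypasses the screen for unit isolation).
mk_call <- function(center, label = "occupancy_like") {
  structure(list(
    region = list(start = (center - 100L) %% 16569L, width = 200L,
                  end = (center - 100L) %% 16569L + 200L, fold = 20,
                  summit_plus = (center - 40L) %% 16569L,
                  summit_minus = (center + 40L) %% 16569L),
    asymmetry = structure(list(best_lag = 80L, corr_best = 0.9,
                               corr_zero = 0.1, score = 0.8,
                               defined = TRUE), class = "asymmetry_result"),
    label = label, mappable_fraction = 1), class = "peak_call")
}
LEN <- 16569L

mk_rec <- function(id, calls, reagent_class = "antibody", reagent_id = "ab1",
                   corroboration = NA_real_, target = "TFX") {
  dataset_record(id, target, "K562", reagent_class, reagent_id,
                 calls = calls, corroboration = corroboration)
}

test_that("site_concordance matches greedily with modular distance", {
  a <- list(mk_call(1000L), mk_call(5000L))
  b <- list(mk_call(1000L), mk_call(5000L))
  expect_equal(site_concordance(a, b, 100, LEN)$overlap, 1.0)
  expect_equal(site_concordance(a, list(mk_call(9000L)), 100, LEN)$overlap,
               0.0)
  ## summits at 100 vs 130: matched at d_max=50, unmatched at d_max=20
  x <- list(mk_call(100L))
  y <- list(mk_call(130L))
  expect_equal(site_concordance(x, y, 50, LEN)$overlap, 1.0)
  expect_equal(site_concordance(x, y, 20, LEN)$overlap, 0.0)
  ## matching is modular across the origin
  w <- list(mk_call(16560L))
  v <- list(mk_call(10L))
  expect_equal(site_concordance(w, v, 50, LEN)$overlap, 1.0)
  ## artifact calls do not participate
  z <- list(mk_call(100L, label = "artifact_like"))
  expect_equal(site_concordance(z, y, 500, LEN)$overlap, 0.0)
})

test_that("tier_evidence reproduces the three canonical scenarios", {
  sites <- list(mk_call(3000L), mk_call(8000L))
  ## 1: antibody + epitope tag, concordant -> orthogonally_replicated
  recs <- list(
    mk_rec("d1", sites, "antibody", "abA"),
    mk_rec("d2", sites, "epitope_tag", "GFP"))
  s1 <- tier_evidence(recs, genome_length = LEN)
  expect_equal(s1$tier, "orthogonally_replicated")
  expect_equal(s1$orthogonal_reagents_with_peaks, 2L)
  expect_false(s1$discordant)

  ## 2: peaks in 2 of 10 datasets, all one antibody -> replicated_same_reagent
  ##    with the discordant flag
  recs2 <- c(list(mk_rec("d01", sites), mk_rec("d02", sites)),
             lapply(3:10, function(i) mk_rec(sprintf("d%02d", i), list())))
  s2 <- tier_evidence(recs2, genome_length = LEN)
  expect_equal(s2$tier, "replicated_same_reagent")
  expect_true(s2$discordant)
  expect_equal(s2$n_with_peaks, 2L)

  ## 3: single corroborated dataset -> single_dataset + model_corroborated
  s3 <- tier_evidence(list(mk_rec("d1", sites, corroboration = 0.8)),
                      genome_length = LEN)
  expect_equal(s3$tier, "single_dataset")
  expect_true(s3$model_corroborated)
  ## below threshold -> not corroborated
  s3b <- tier_evidence(list(mk_rec("d1", sites, corroboration = 0.3)),
                       genome_length = LEN)
  expect_false(s3b$model_corroborated)
})

test_that("tier is invariant to dataset order; no-peak data never raises it", {
  sites <- list(mk_call(3000L))
  recs <- list(
    mk_rec("a", sites, "antibody", "abA"),
    mk_rec("b", sites, "epitope_tag", "GFP"),
    mk_rec("c", list(), "antibody", "abB"))
  base <- tier_evidence(recs, genome_length = LEN)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    s <- tier_evidence(recs[perm], genome_length = LEN)
    expect_equal(s$tier, base$tier)
    expect_equal(s$discordant, base$discordant)
    expect_equal(s$orthogonal_reagents_with_peaks,
                 base$orthogonal_reagents_with_peaks)
  }
  ## adding a no-peak dataset: tier unchanged, discordant set
  s_plus <- tier_evidence(c(recs[1:2], list(mk_rec("d", list()))),
                          genome_length = LEN)
  expect_equal(s_plus$tier, "orthogonally_replicated")
  expect_true(s_plus$discordant)
})

test_that("lot sensitivity can split a reagent identity", {
  sites <- list(mk_call(3000L))
  r1 <- dataset_record("x1", "TFX", "K562", "antibody", "abA", lot = "L1",
                       calls = sites)
  r2 <- dataset_record("x2", "TFX", "HepG2", "antibody", "abA", lot = "L2",
                       calls = sites)
  ins <- tier_evidence(list(r1, r2), genome_length = LEN)
  expect_equal(ins$tier, "replicated_same_reagent")
  sens <- tier_evidence(list(r1, r2), lot_sensitive = TRUE,
                        genome_length = LEN)
  expect_equal(sens$tier, "orthogonally_replicated")
})

test_that("tier_evidence rejects mixed targets and duplicate ids", {
  expect_error(tier_evidence(list(mk_rec("a", list(), target = "TF1"),
                                  mk_rec("b", list(), target = "TF2")),
                             genome_length = LEN), "mix targets")
  expect_error(tier_evidence(list(mk_rec("a", list()), mk_rec("a", list())),
                             genome_length = LEN), "unique")
})

test_that("cluster_profiles: identical pair merges first, dist is metric-ish", {
  set.seed(31)
  base <- abs(rnorm(500))
  m <- rbind(profileA = base, profileB = base,
             flat = rep(1, 500),
             other = abs(rnorm(500)))
  cl <- cluster_profiles(m)
  ## the identical pair merges first at height ~ 0
  first <- cl$merge[1, ]
  expect_setequal(-first, which(rownames(m) %in% c("profileA", "profileB")))
  expect_lt(cl$height[1], 1e-12)
  ## adjacency of the planted pair
  pos <- match(c("profileA", "profileB"), cl$order)
  expect_equal(abs(diff(pos)), 1L)
  ## distance matrix: symmetric, zero diagonal
  expect_equal(cl$dist, t(cl$dist))
  expect_true(all(diag(cl$dist) == 0))
  ## duplicating a track leaves other pairwise distances unchanged
  m2 <- rbind(m, profileA2 = base)
  cl2 <- cluster_profiles(m2)
  keep <- c("profileA", "flat", "other")
  expect_equal(cl2$dist[keep, keep], cl$dist[keep, keep], tolerance = 1e-12)

  ## zero-total track excluded with warning; < 2 tracks errors
  m3 <- rbind(a = base, b = abs(rnorm(500)), z = rep(0, 500))
  expect_warning(cl3 <- cluster_profiles(m3), "zero-total")
  expect_length(cl3$order, 2L)
  expect_error(cluster_profiles(m[1, , drop = FALSE]), "at least 2")
})

test_that("two datasets sharing planted sites cluster together", {
  set.seed(42)
  g <- generate_circular_genome(8000, 0.44, seed = 41)
  shared <- truth_sites(c(2000L, 6000L), "+", NA, 25, "occupancy")
  profs <- list()
  for (i in 1:2) {  # two datasets with the shared sites
    a <- simulate_reads(g, shared, sim_config(20000, seed = 500 + i))
    cv <- coverage_track(a, g$length)
    profs[[sprintf("shared%d", i)]] <- cv$plus + cv$minus
  }
  for (i in 1:8) {  # eight datasets with their own random site pairs
    own <- truth_sites(sort(sample(seq(500L, 7500L, by = 250L), 2)), "+",
                       NA, 25, "occupancy")
    a <- simulate_reads(g, own, sim_config(20000, seed = 600 + i))
    cv <- coverage_track(a, g$length)
    profs[[sprintf("own%d", i)]] <- cv$plus + cv$minus
  }
  set.seed(42)
  cl <- cluster_profiles(do.call(rbind, profs))
  pos <- match(c("shared1", "shared2"), cl$order)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("evidence_table flattens summaries", {
  sites <- list(mk_call(3000L))
  s1 <- tier_evidence(list(mk_rec("d1", sites, corroboration = 0.9)),
                      genome_length = LEN)
  s2 <- tier_evidence(list(mk_rec("d2", list(), target = "TFY")),
                      genome_length = LEN)
  tb <- evidence_table(list(s1, s2))
  expect_equal(nrow(tb), 2L)
  expect_equal(tb$tier, c("single_dataset", "no_evidence"))
  expect_equal(tb$model_corroborated, c(TRUE, FALSE))
})
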