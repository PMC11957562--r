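test_that("call_candidates applies the fold rule on constructed tracks", {
  len <- 2000L
  ## constant track: fold 1 everywhere, no candidates
  flat <- stranded_track("g", "coverage", rep(5, len), rep(5, len))
  expect_length(call_candidates(flat), 0L)

  ## one 400 bp block at 100x over background 5 -> exactly one candidate
  plus <- rep(5, len)
  plus[101:500] <- 500
  tr <- stranded_track("g", "coverage", plus, rep(5, len))
  cands <- call_candidates(tr)
  expect_length(cands, 1L)
  expect_lte(cands[[1]]$start, 100L)
  expect_gte(cands[[1]]$end, 500L)
  expect_gt(cands[[1]]$fold, 30)

  ## block spanning the origin -> one modular candidate, not two
  plus2 <- rep(5, len)
  plus2[c(1901:2000, 1:100)] <- 500
  tr2 <- stranded_track("g", "coverage", plus2, rep(5, len))
  c2 <- call_candidates(tr2)
  expect_length(c2, 1L)
  expect_gt(c2[[1]]$end, len)  # wraps

  ## all-zero track -> empty list, message not error
  zero <- stranded_track("g", "coverage", rep(0, len), rep(0, len))
  expect_message(out <- call_candidates(zero), "no candidates")
  expect_length(out, 0L)

  ## zero background with nonzero peaks -> floored at 1
  spike <- rep(0, len)
  spike[500:600] <- 50
  trs <- stranded_track("g", "coverage", spike, rep(0, len))
  expect_message(cs <- call_candidates(trs), "floored")
  expect_length(cs, 1L)
})

test_that("raising fold_min never increases candidate count", {
  w <- make_test_world(seed = 2)
  cov <- coverage_track(w$aset, w$genome$length)
  n_prev <- Inf
  for (fm in c(2, 3, 5, 10, 50)) {
    n <- length(call_candidates(cov, params = screen_params(fold_min = fm)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("asymmetry recovers lag on delta and symmetric profiles", {
  len <- 2000L
  plus <- rep(0, len)
  minus <- rep(0, len)
  plus[101] <- 50   # delta at 100
  minus[301] <- 50  # delta at 300
  tr <- stranded_track("g", "five_prime", plus, minus)
  region <- list(start = 80L, width = 250L, end = 330L)
  a <- asymmetry(tr, region, max_lag = 400)
  expect_equal(a$best_lag, 200L)
  expect_gt(a$corr_best, 0.9)
  expect_lt(abs(a$corr_zero), 0.2)

  ## identical strands: best lag 0, score ~ 0
  sym <- stranded_track("g", "five_prime", plus, plus)
  s <- asymmetry(sym, region, max_lag = 400)
  expect_equal(s$best_lag, 0L)
  expect_lt(abs(s$score), 1e-6)

  ## a strand with no reads -> undefined
  half <- stranded_track("g", "five_prime", plus, rep(0, len))
  h <- asymmetry(half, region, max_lag = 400)
  expect_false(h$defined)
  expect_true(is.na(h$score))
})

test_that("simulated occupancy site recovers lag near fragment length", {
  g <- generate_circular_genome(10000, 0.44, seed = 6)
  s <- truth_sites(5000, "+", NA, 20, "occupancy")
  aset <- simulate_reads(g, s, sim_config(20000, fragment_length_mean = 200,
                                          background_fraction = 0,
                                          seed = 31))
  fp <- five_prime_track(aset, g$length)
  region <- list(start = 4800L, width = 400L, end = 5200L)
  a <- asymmetry(fp, region, max_lag = 400)
  expect_gte(a$best_lag, 180L)
  expect_lte(a$best_lag, 220L)
  expect_gt(a$score, 0.3)
})

test_that("classify applies the label rules", {
  len <- 16569L
  region <- list(start = 100L, width = 200L, end = 300L,
                 fold = 50, summit_plus = 150L, summit_minus = 250L)
  asym_occ <- structure(list(best_lag = 200L, corr_best = 0.9,
                             corr_zero = 0.3, score = 0.6, defined = TRUE),
                        class = "asymmetry_result")
  asym_art <- structure(list(best_lag = 0L, corr_best = 0.9,
                             corr_zero = 0.88, score = 0.02, defined = TRUE),
                        class = "asymmetry_result")
  p <- screen_params()
  expect_equal(classify(region, asym_occ, NULL, p,
                        genome_length = len)$label, "occupancy_like")
  expect_equal(classify(region, asym_art, NULL, p,
                        genome_length = len)$label, "artifact_like")
  ## inside the mask: masked regardless of score
  masks <- data.frame(start = 50L, width = 400L, label = "D-loop")
  expect_equal(classify(region, asym_occ, masks, p,
                        genome_length = len)$label, "masked")
  ## undefined asymmetry -> ambiguous
  asym_na <- structure(list(best_lag = NA_integer_, corr_best = NA_real_,
                            corr_zero = NA_real_, score = NA_real_,
                            defined = FALSE), class = "asymmetry_result")
  expect_equal(classify(region, asym_na, NULL, p,
                        genome_length = len)$label, "ambiguous")
  ## plausible lag but weak score -> artifact_like; strong score but lag
  ## beyond lag_max -> ambiguous
  asym_big <- structure(list(best_lag = 450L, corr_best = 0.9,
                             corr_zero = 0.2, score = 0.7, defined = TRUE),
                        class = "asymmetry_result")
  expect_equal(classify(region, asym_big, NULL, p,
                        genome_length = len)$label, "ambiguous")
})

test_that("screen_dataset end to end: sites found, artifact rejected", {
  w <- make_test_world(seed = 3)
  masks <- data.frame(start = 5950L, width = 500L, label = "D-loop")
  res <- screen_dataset(w$aset, w$genome, masks = masks)
  occ <- res$report[res$report$label == "occupancy_like", ]
  expect_equal(nrow(occ), 2L)
  for (p in c(1500L, 4000L)) {
    expect_true(any(abs(occ$center - p) <= 50))
  }
  ## the artifact site at 300 is inside the wrap-spanning mask
  art_rows <- res$report[res$report$label %in% c("masked", "artifact_like"), ]
  expect_gte(nrow(art_rows), 1L)
  expect_false(any(abs(occ$center - 300) <= 100))

  ## control library: no occupancy calls
  ctrl <- simulate_reads(w$genome, w$sites,
                         sim_config(20000, background_fraction = 0.5,
                                    seed = 77, control = TRUE))
  resc <- screen_dataset(ctrl, w$genome, masks = masks)
  expect_equal(sum(resc$report$label == "occupancy_like"), 0L)

  ## empty alignment set -> empty calls, no crash
  empty <- alignment_set(w$genome$name,
                         data.frame(start = integer(0), length = integer(0),
                                    strand = character(0)))
  rese <- suppressMessages(screen_dataset(empty, w$genome, masks = masks))
  expect_length(rese$calls, 0L)
})

test_that("screen is rotation equivariant", {
  w <- make_test_world(seed = 4)
  masks <- data.frame(start = 5950L, width = 500L, label = "D-loop")
  r <- 1234L
  res <- screen_dataset(w$aset, w$genome, masks = masks)
  rot_masks <- data.frame(start = (masks$start - r) %% w$genome$length,
                          width = masks$width, label = masks$label)
  res_r <- screen_dataset(rotate_reads(w$aset, r, w$genome$length),
                          rotate_genome(w$genome, r), masks = rot_masks)
  expect_equal(nrow(res$report), nrow(res_r$report))
  expect_setequal((res$report$center - r) %% w$genome$length,
                  res_r$report$center)
  expect_setequal(res$report$label, res_r$report$label)
})

test_that("calls BED output splits wrap-spanning calls", {
  len <- 1000L
  cl <- structure(list(
    region = list(start = 950L, width = 100L, end = 1050L, fold = 10,
                  summit_plus = 960L, summit_minus = 30L),
    asymmetry = structure(list(best_lag = 70L, corr_best = 0.8,
                               corr_zero = 0.1, score = 0.7,
                               defined = TRUE), class = "asymmetry_result"),
    label = "occupancy_like", mappable_fraction = 1), class = "peak_call")
  path <- withr::local_tempfile(fileext = ".bed")
  write_calls_bed(list(cl), path, "chrM", len)
  body <- readLines(path)[-1]
  expect_length(body, 2L)
  f <- do.call(rbind, strsplit(body, "\t"))
  expect_equal(as.integer(f[, 2]), c(950L, 0L))
  expect_equal(as.integer(f[, 3]), c(1000L, 50L))
  expect_equal(unique(f[, 4]), "call001")
})
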