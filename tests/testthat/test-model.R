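tiny_cfg <- function(use_control = FALSE) {
  profile_model_config(input_length = 514, output_length = 250,
                       n_conv_layers = 4, n_filters = 16,
                       use_control = use_control)
}

test_that("config invariants and receptive-field arithmetic", {
  cfg <- profile_model_config()
  expect_equal(cfg$input_length, 2114L)
  expect_equal(cfg$output_length, 1000L)
  ## trunk RF = 21 + sum_{l=2..9} 2 * 2^(l-1) = 21 + 2*510
  expect_equal(receptive_field(cfg), 21 + 2 * (2 + 4 + 8 + 16 + 32 + 64 +
                                                 128 + 256))
  expect_error(profile_model_config(input_length = 500,
                                    output_length = 1000), "exceed")
  expect_error(profile_model_config(first_kernel = 20), "odd")
  expect_error(profile_model_config(n_conv_layers = 1), ">= 2")
})

test_that("model emits 2 x output_length logits; control contract holds", {
  ns <- asNamespace("mitochip")
  cfg <- tiny_cfg(use_control = TRUE)
  m <- build_model(cfg, seed = 1)
  set.seed(4)
  x <- one_hot(paste(sample(c("A", "C", "G", "T"), 514, TRUE),
                     collapse = ""))
  fw <- ns$nn_forward(m$params, cfg, x, matrix(1, 2, 250), 2)
  expect_equal(dim(fw$logits), c(2L, 250L))
  expect_length(fw$log_total, 1L)
  ## softmax normalization across both strands jointly
  p <- exp(fw$logits - max(fw$logits))
  expect_equal(sum(p / sum(p)), 1, tolerance = 1e-12)
  ## use_control = FALSE: predictions are a function of sequence alone
  cfg0 <- tiny_cfg(use_control = FALSE)
  m0 <- build_model(cfg0, seed = 1)
  a <- ns$nn_forward(m0$params, cfg0, x, matrix(5, 2, 250), 9)
  b <- ns$nn_forward(m0$params, cfg0, x, NULL, 0)
  expect_equal(a$logits, b$logits)
  expect_equal(a$log_total, b$log_total)
})

test_that("multinomial NLL matches analytic cases", {
  ## uniform probabilities, 10 counts over 2x1000 bins: 10 * ln(2000)
  logits <- matrix(0, 2, 1000)
  target <- matrix(0, 2, 1000)
  target[1, c(5, 17, 400)] <- c(3, 3, 4)
  expect_equal(multinomial_profile_nll(logits, target), 10 * log(2000),
               tolerance = 1e-9)
  ## all mass on one bin with probability -> 1: NLL -> 0
  l2 <- matrix(c(100, 0, 0, 0), 2, 2)
  t2 <- matrix(c(7, 0, 0, 0), 2, 2)
  expect_lt(multinomial_profile_nll(l2, t2), 1e-6)
  ## counts (3,1) against p = (0.75, 0.25)
  l3 <- matrix(log(c(0.75, 0.25)), 1)
  t3 <- matrix(c(3, 1), 1)
  expect_equal(multinomial_profile_nll(l3, t3),
               -(3 * log(0.75) + log(0.25)), tolerance = 1e-9)
  expect_error(multinomial_profile_nll(matrix(0, 2, 3), matrix(0, 2, 4)),
               "shape")
})

test_that("counts MSE matches analytic cases", {
  expect_equal(counts_mse(c(1, 2), c(1, 2)), 0)
  expect_equal(counts_mse(log(100), log(1000)), log(10)^2,
               tolerance = 1e-9)
  expect_equal(counts_mse(c(1, 3), c(0, 0)), 5)
  expect_error(counts_mse(Inf, 0), "finite")
})

test_that("training-set construction: ratio, outliers, GC match, folds", {
  sim <- simulate_motif_world(n_contigs = 3, contig_length = 4000,
                              sites_per_contig = 5, n_reads = 12000,
                              seed = 2)
  cfg <- tiny_cfg()
  tcfg <- training_config(seed = 2, n_folds = 3)
  tset <- make_training_set(sim$peaks, sim$genomes, sim$tracks,
                            config = cfg, tcfg = tcfg)
  ex <- tset$examples
  n_pk <- sum(ex$is_peak)
  n_np <- sum(!ex$is_peak)
  ## 3:1 ratio (floor of peaks / 3)
  expect_equal(n_np, floor(n_pk / 3))
  ## GC matching within tolerance of the cycled matched peak
  gc_pk <- ex$gc[ex$is_peak]
  gc_np <- ex$gc[!ex$is_peak]
  for (i in seq_len(n_np)) {
    expect_lte(abs(gc_np[i] - gc_pk[((i - 1) %% n_pk) + 1]),
               tcfg$gc_tol + 1e-9)
  }
  ## non-peak windows avoid peak space
  for (i in which(!ex$is_peak)) {
    sites <- sim$sites[[ex$contig[i]]]$position
    expect_gt(min(abs(ex$center[i] - sites)), cfg$output_length / 2)
  }
  ## fold keys are contigs
  expect_setequal(unique(ex$fold_key), names(sim$genomes))

  ## outlier rule: 1.2 x Q99 on constructed counts. Peak i carries total
  ## counts i (i = 1..99) plus one extreme peak with 1000; Q99 of that
  ## vector is 108.01 (type-7), so only the extreme peak exceeds 1.2 x Q99.
  peaks <- data.frame(contig = "c1",
                      start = seq(0, 99) * 250L,
                      end = seq(0, 99) * 250L + 50L)
  g1 <- generate_circular_genome(30000, 0.5, seed = 9, name = "c1")
  plus <- rep(0, 30000)
  centers <- (peaks$start + peaks$end) %/% 2L
  plus[centers + 1L] <- c(seq_len(99), 1000)
  trk <- list(c1 = stranded_track("c1", "five_prime", plus, rep(0, 30000)))
  ts2 <- make_training_set(peaks, list(c1 = g1), trk, config = cfg,
                           tcfg = training_config(n_folds = 1, seed = 1,
                                                  gc_tol = 0.1))
  kept <- ts2$examples$total_counts[ts2$examples$is_peak]
  expect_length(kept, 99L)
  expect_false(1000 %in% kept)
  expect_true(all(sort(kept) == seq_len(99)))
})

test_that("jitter draws stay within the configured bound", {
  tcfg <- training_config(jitter_max = 128, seed = 5)
  draws <- mitochip:::with_seed(1, sample(-tcfg$jitter_max:tcfg$jitter_max,
                                          1000, replace = TRUE))
  expect_true(all(abs(draws) <= 128))
  ## materialization applies the requested shift exactly
  sim <- simulate_motif_world(n_contigs = 2, contig_length = 3000,
                              sites_per_contig = 4, n_reads = 8000,
                              seed = 3)
  cfg <- tiny_cfg()
  tset <- make_training_set(sim$peaks, sim$genomes, sim$tracks,
                            config = cfg,
                            tcfg = training_config(n_folds = 2, seed = 1))
  e0 <- materialize_example(tset, 1, jitter = 0L)
  e1 <- materialize_example(tset, 1, jitter = 10L)
  expect_equal(e0$target[, 11:250], e1$target[, 1:240])
})

test_that("reverse-complement materialization swaps strands coherently", {
  sim <- simulate_motif_world(n_contigs = 2, contig_length = 3000,
                              sites_per_contig = 4, n_reads = 8000,
                              seed = 4)
  tset <- make_training_set(sim$peaks, sim$genomes, sim$tracks,
                            config = tiny_cfg(),
                            tcfg = training_config(n_folds = 2, seed = 1))
  fwd <- materialize_example(tset, 1, rc = FALSE)
  rc <- materialize_example(tset, 1, rc = TRUE)
  expect_equal(rc$target[1, ], rev(fwd$target[2, ]))
  expect_equal(rc$target[2, ], rev(fwd$target[1, ]))
  ## one-hot RC: A row of fwd equals reversed T row of rc
  expect_equal(rc$x[4, ], rev(fwd$x[1, ]))
  expect_equal(rc$target_log_total, fwd$target_log_total)
})

test_that("fold assignment partitions contigs disjointly", {
  keys <- c("c1", "c2", "c3", "c4", "c5")
  f <- assign_folds(keys, 5)
  expect_length(unique(f), 5L)
  expect_setequal(names(f), keys)
  expect_error(assign_folds("only_one", 5), ">= 2 contigs")
})

test_that("zero-epoch training returns the initialization", {
  sim <- simulate_motif_world(n_contigs = 3, contig_length = 3000,
                              sites_per_contig = 4, n_reads = 6000,
                              seed = 5)
  cfg <- tiny_cfg()
  tcfg <- training_config(n_folds = 3, seed = 9, epochs = 0)
  tset <- make_training_set(sim$peaks, sim$genomes, sim$tracks,
                            config = cfg, tcfg = tcfg)
  fit <- train_profile_model(tset, tcfg, folds_to_run = 1L)
  init <- build_model(cfg, seed = tcfg$seed + 1L)
  expect_equal(fit$fits[[1]]$model$params, init$params)
})

test_that("prediction tiling covers every base exactly; constant model is flat", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 2)
  ## zero out all weights: constant (uniform) logits regardless of sequence
  m$params <- rapply(m$params, function(w) w * 0, how = "replace")
  m$trained <- TRUE
  g <- generate_circular_genome(16569, 0.44, seed = 12)
  pred <- predict_circular(m, g)
  expect_length(pred$plus, 16569L)
  expect_length(pred$minus, 16569L)
  expect_equal(attr(pred, "provenance")$n_tiles, ceiling(16569 / 250))
  expect_true(all(is.finite(pred$plus)) && all(pred$plus >= 0))
  ## flat within float tolerance
  expect_lt(diff(range(pred$plus)), 1e-10)
  expect_lt(diff(range(pred$minus)), 1e-10)
  ## rotation equivariance with matched tile offsets
  r <- 250L  # a multiple of the tile step keeps tiling aligned
  pr <- predict_circular(m, rotate_genome(g, r))
  expect_equal(pr$plus, rotate_vec_test(pred$plus, r), tolerance = 1e-9)
})

test_that("forward/RC averaging is a no-op on palindromic windows", {
  ns <- asNamespace("mitochip")
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 3)
  ## reverse-complement-symmetric input window
  set.seed(14)
  half <- paste(sample(c("A", "C", "G", "T"), 257, TRUE), collapse = "")
  rc_half <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(half)))
  pal <- paste0(half, rc_half)
  expect_equal(nchar(pal), 514L)
  x <- one_hot(pal)
  expect_equal(unname(ns$.rc_onehot(x)), unname(x))  # genuinely palindromic
  ## the forward and RC passes see identical inputs, so they agree exactly
  fw <- ns$nn_forward(m$params, cfg, x)
  fr <- ns$nn_forward(m$params, cfg, ns$.rc_onehot(x))
  expect_equal(fw$logits, fr$logits, tolerance = 1e-12)
  expect_equal(fw$log_total, fr$log_total, tolerance = 1e-12)
  ## the averaged profile is RC-symmetric, so averaging it again is a no-op
  soft <- function(z) {
    z <- as.numeric(z); matrix(exp(z - max(z)) / sum(exp(z - max(z))), 2)
  }
  avg <- (soft(fw$logits) + ns$.rc_profile(soft(fr$logits))) / 2
  expect_equal(ns$.rc_profile(avg), avg, tolerance = 1e-12)
  expect_equal((avg + ns$.rc_profile(avg)) / 2, avg, tolerance = 1e-12)
})

test_that("prediction averaging makes the pipeline RC-equivariant", {
  ns <- asNamespace("mitochip")
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 5)
  set.seed(15)
  s <- paste(sample(c("A", "C", "G", "T"), 514, TRUE), collapse = "")
  x <- one_hot(s)
  avg_pred <- function(xin) {
    soft <- function(z) {
      z <- as.numeric(z); matrix(exp(z - max(z)) / sum(exp(z - max(z))), 2)
    }
    fw <- ns$nn_forward(m$params, cfg, xin)
    fr <- ns$nn_forward(m$params, cfg, ns$.rc_onehot(xin))
    (soft(fw$logits) + ns$.rc_profile(soft(fr$logits))) / 2
  }
  p <- avg_pred(x)
  p_rc <- avg_pred(ns$.rc_onehot(x))
  expect_equal(p_rc, ns$.rc_profile(p), tolerance = 1e-12)
})

test_that("corroboration_score follows the asymmetric matching criterion", {
  len <- 5000L
  mk_call <- function(center) {
    structure(list(
      region = list(start = center - 100L, width = 200L,
                    end = center + 100L, fold = 20,
                    summit_plus = center - 40L, summit_minus = center + 40L),
      asymmetry = structure(list(best_lag = 80L, corr_best = 0.9,
                                 corr_zero = 0.1, score = 0.8,
                                 defined = TRUE),
                            class = "asymmetry_result"),
      label = "occupancy_like", mappable_fraction = 1),
      class = "peak_call")
  }
  ## predicted track with strong peaks at 1000 and 3000 only
  plus <- rep(0.01, len)
  for (p in c(1000, 3000)) plus[(p - 10):(p + 10)] <- 5
  pred <- stranded_track("g", "predicted", plus, plus)
  ## both observed peaks near predicted -> 1.0
  r1 <- corroboration_score(list(mk_call(1010L), mk_call(2990L)), pred)
  expect_equal(r1$score, 1.0)
  ## no overlap -> 0.0
  r0 <- corroboration_score(list(mk_call(2000L)), pred)
  expect_equal(r0$score, 0.0)
  ## 2 of 4 matched -> 0.5; unmatched predicted peaks don't penalize
  r2 <- corroboration_score(list(mk_call(1000L), mk_call(3000L),
                                 mk_call(2000L), mk_call(4000L)), pred)
  expect_equal(r2$score, 0.5)
  ## empty call list -> undefined, flagged
  re <- corroboration_score(list(), pred)
  expect_true(is.na(re$score))
  expect_false(re$defined)
})
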