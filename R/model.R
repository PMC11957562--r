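#' Sequence-to-profile model configuration
#'
#' Architecture of the base-resolution profile model: a trunk of
#' `n_conv_layers` convolutions with ReLU activations — a wide first layer
#' (kernel `first_kernel`, no dilation) followed by kernel-3 layers whose
#' dilation doubles at every layer, all zero-padded with additive residual
#' skips — feeding two heads. The profile head is a wide (kernel
#' `profile_kernel`, no padding) convolution whose output is center-cropped
#' to `output_length`, stacked with the control profile and passed through a
#' size-1 convolution to give two strands of logits, normalized by a single
#' softmax over both strands jointly. The counts head global-average-pools
#' the trunk, passes a dense layer, concatenates the control log total and
#' predicts the log of total counts over both strands.
#'
#' @param input_length one-hot input window, bases (default 2114).
#' @param output_length predicted window, bases (default 1000).
#' @param n_conv_layers trunk depth (default 9).
#' @param n_filters filters per layer (default 64).
#' @param first_kernel first-layer kernel (default 21, odd).
#' @param dilated_kernel dilated-layer kernel (default 3, odd).
#' @param profile_kernel profile-head kernel (default 75, odd).
#' @param use_control whether control (input experiment) tracks are wired in;
#'   with `FALSE`, zeroed control inputs leave predictions a function of
#'   sequence alone.
#' @param counts_loss_weight weight of the counts MSE in the total loss.
#' @return a list of class `profile_model_config`.
#' @export
profile_model_config <- function(input_length = 2114, output_length = 1000,
                                 n_conv_layers = 9, n_filters = 64,
                                 first_kernel = 21, dilated_kernel = 3,
                                 profile_kernel = 75, use_control = TRUE,
                                 counts_loss_weight = 1) {
  if (input_length <= output_length) stop("input_length must exceed output_length")
  if (n_conv_layers < 2) stop("n_conv_layers must be >= 2")
  for (kk in c(first_kernel, dilated_kernel, profile_kernel)) {
    if (kk %% 2 != 1) stop("kernel sizes must be odd")
  }
  if (counts_loss_weight < 0) stop("counts_loss_weight must be >= 0")
  if ((input_length - (profile_kernel - 1) - output_length) %% 2 != 0) {
    stop("input/output/profile_kernel combination does not center-crop evenly")
  }
  structure(list(input_length = as.integer(input_length),
                 output_length = as.integer(output_length),
                 n_conv_layers = as.integer(n_conv_layers),
                 n_filters = as.integer(n_filters),
                 first_kernel = as.integer(first_kernel),
                 dilated_kernel = as.integer(dilated_kernel),
                 dilation_base = 2L,
                 profile_kernel = as.integer(profile_kernel),
                 use_control = isTRUE(use_control),
                 counts_loss_weight = counts_loss_weight),
            class = "profile_model_config")
}

#' Receptive field of the trunk
#'
#' `first_kernel + sum over dilated layers of (kernel-1) * 2^(l-1)` — the
#' genomic span that can influence one trunk output position.
#'
#' @param config a [profile_model_config()].
#' @return receptive field in bases.
#' @export
receptive_field <- function(config) {
  ls <- 2:config$n_conv_layers
  config$first_kernel +
    sum((config$dilated_kernel - 1L) * config$dilation_base^(ls - 1L))
}

#' Build an untrained profile model
#'
#' @param config a [profile_model_config()].
#' @param seed initialization seed.
#' @return an object of class `profile_model`.
#' @export
build_model <- function(config, seed = 1) {
  structure(list(config = config, params = nn_init_params(config, seed),
                 trained = FALSE, seed = seed),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %d layers x %d filters, in %d / out %d, %s\n",
              x$config$n_conv_layers, x$config$n_filters,
              x$config$input_length, x$config$output_length,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' One-hot encode a DNA string
#'
#' Rows A, C, G, T; `N` encodes as an all-zero column.
#'
#' @param s DNA string.
#' @return 4 x nchar(s) numeric matrix.
#' @export
one_hot <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  m <- matrix(0, 4, length(chars),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  code <- match(chars, c("A", "C", "G", "T"))
  ok <- which(!is.na(code))
  if (length(ok)) m[cbind(code[ok], ok)] <- 1
  m
}

## reverse-complement a one-hot matrix (A<->T, C<->G, reverse positions)
.rc_onehot <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

## strand-swap + reverse a 2 x L profile (row 1 = plus, row 2 = minus)
.rc_profile <- function(p) p[2:1, rev(seq_len(ncol(p))), drop = FALSE]

#' Multinomial profile negative log-likelihood
#'
#' The two strands of logits are flattened and normalized by a single
#' softmax; the loss is `-sum(counts * log p)` over all `2 * output_length`
#' bins.
#'
#' @param logits 2 x L numeric matrix (or vector) of profile logits.
#' @param target matching matrix/vector of non-negative observed counts.
#' @return non-negative scalar loss.
#' @export
multinomial_profile_nll <- function(logits, target) {
  if (length(logits) != length(target)) stop("shape mismatch in profile NLL")
  if (any(target < 0)) stop("target counts must be >= 0")
  z <- as.numeric(logits)
  z <- z - max(z)
  logp <- z - log(sum(exp(z)))
  -sum(as.numeric(target) * logp)
}

## gradient of the NLL w.r.t. the logits: total * softmax(z) - counts
.profile_nll_grad <- function(logits, target) {
  z <- as.numeric(logits)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  matrix(sum(target) * p - as.numeric(target), nrow = nrow(logits))
}

#' Mean squared error of log total counts
#'
#' @param predicted_log_total,target_log_total numeric vectors (batch).
#' @return mean squared error.
#' @export
counts_mse <- function(predicted_log_total, target_log_total) {
  if (!all(is.finite(predicted_log_total)) ||
      !all(is.finite(target_log_total))) {
    stop("counts_mse requires finite inputs")
  }
  mean((predicted_log_total - target_log_total)^2)
}

#' Training configuration
#'
#' @param peak_ratio peaks per non-peak example (default 3, i.e. a 3:1
#'   peak:non-peak ratio).
#' @param outlier_quantile,outlier_multiplier peaks whose total counts
#'   exceed `outlier_multiplier` times the `outlier_quantile` quantile are
#'   removed (defaults 0.99 and 1.2).
#' @param jitter_max peak windows are shifted by a fresh uniform draw in
#'   `[-jitter_max, jitter_max]` each epoch (default 128).
#' @param rc_augment whether every window also contributes its reverse
#'   complement with strand-swapped targets.
#' @param n_folds cross-validation folds, grouped by contig so no window
#'   ever crosses train/validation/test (default 5).
#' @param gc_tol GC-content matching tolerance for non-peak windows.
#' @param seed training seed.
#' @param epochs,batch_size,lr,patience optimizer settings (adaptive-moment
#'   optimizer; early stopping on validation loss).
#' @return a list of class `training_config`.
#' @export
training_config <- function(peak_ratio = 3, outlier_quantile = 0.99,
                            outlier_multiplier = 1.2, jitter_max = 128,
                            rc_augment = TRUE, n_folds = 5, gc_tol = 0.02,
                            seed = 1, epochs = 100, batch_size = 64,
                            lr = 1e-3, patience = 5) {
  if (peak_ratio < 1) stop("peak_ratio expresses peaks:nonpeaks with peaks >= nonpeaks")
  if (jitter_max < 0) stop("jitter_max must be >= 0")
  structure(list(peak_ratio = peak_ratio,
                 outlier_quantile = outlier_quantile,
                 outlier_multiplier = outlier_multiplier,
                 jitter_max = as.integer(jitter_max),
                 rc_augment = isTRUE(rc_augment),
                 n_folds = as.integer(n_folds), gc_tol = gc_tol,
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience)),
            class = "training_config")
}

.gc_window <- function(genome, center, width) {
  s <- subseq_circular(genome, center - width %/% 2L, width)
  mean(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C"))
}

.window_counts <- function(track, center, width) {
  idx <- circ_index(center - width %/% 2L, width, length(track$plus))
  sum(track$plus[idx]) + sum(track$minus[idx])
}

#' Construct a training set from peaks, genomes and 5'-end tracks
#'
#' Implements the training-set construction rules: outlier peaks (total
#' window counts above `outlier_multiplier` times the `outlier_quantile`
#' quantile) are removed; GC-matched non-peak windows are sampled from
#' peak-free space at a peaks:non-peaks ratio of `peak_ratio`:1; the fold
#' key is the contig, so cross-validation folds never share a contig.
#' Windows are materialized lazily (see [materialize_example()]) so that
#' jitter and reverse-complement augmentation can be drawn fresh per epoch.
#'
#' @param peaks data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), e.g. read from a BED file of reproducible peaks.
#' @param genomes named list of [circular_genome()] objects.
#' @param tracks named list of 5'-end [stranded_track()]s, same names.
#' @param control_tracks optional named list of control 5'-end tracks.
#' @param config a [profile_model_config()] (window sizes).
#' @param tcfg a [training_config()].
#' @return an object of class `training_set` with an `examples` data.frame
#'   (`contig`, `center`, `is_peak`, `gc`, `total_counts`, `fold_key`).
#' @export
make_training_set <- function(peaks, genomes, tracks, control_tracks = NULL,
                              config, tcfg = training_config()) {
  if (!all(peaks$contig %in% names(genomes))) {
    stop("peaks reference contigs absent from the genome set")
  }
  centers <- (peaks$start + peaks$end) %/% 2L
  counts <- vapply(seq_len(nrow(peaks)), function(i) {
    .window_counts(tracks[[peaks$contig[i]]], centers[i],
                   config$output_length)
  }, numeric(1))
  cutoff <- tcfg$outlier_multiplier *
    stats::quantile(counts, tcfg$outlier_quantile, names = FALSE, type = 7)
  keep <- counts <= cutoff
  peaks <- peaks[keep, , drop = FALSE]
  centers <- centers[keep]
  counts <- counts[keep]
  gc_peak <- vapply(seq_along(centers), function(i) {
    .gc_window(genomes[[peaks$contig[i]]], centers[i], config$input_length)
  }, numeric(1))
  n_nonpeak <- floor(length(centers) / tcfg$peak_ratio)
  ## candidate non-peak centers on a grid, away from any peak window
  nonpeak <- data.frame(contig = character(0), center = integer(0),
                        gc = numeric(0))
  if (n_nonpeak > 0) {
    cand <- do.call(rbind, lapply(names(genomes), function(g) {
      len <- genomes[[g]]$length
      grid <- seq.int(0L, len - 1L, by = max(25L, config$output_length %/% 8L))
      pk <- peaks[peaks$contig == g, , drop = FALSE]
      free <- vapply(grid, function(p) {
        if (nrow(pk) == 0) return(TRUE)
        ## window [p - out/2, p + out/2) must not touch any peak interval
        all(circ_dist(p, (pk$start + pk$end) %/% 2L, len) >
              (config$output_length + (pk$end - pk$start)) / 2)
      }, logical(1))
      if (!any(free)) return(NULL)
      data.frame(contig = g, center = grid[free], stringsAsFactors = FALSE)
    }))
    if (is.null(cand) || nrow(cand) == 0) {
      stop("insufficient peak-free space: no candidate non-peak windows")
    }
    cand$gc <- vapply(seq_len(nrow(cand)), function(i) {
      .gc_window(genomes[[cand$contig[i]]], cand$center[i],
                 config$input_length)
    }, numeric(1))
    used <- logical(nrow(cand))
    sel <- integer(0)
    shortfall <- 0L
    for (i in seq_len(n_nonpeak)) {
      target_gc <- gc_peak[((i - 1L) %% length(gc_peak)) + 1L]
      ok <- which(!used & abs(cand$gc - target_gc) <= tcfg$gc_tol)
      if (length(ok) == 0) {
        shortfall <- shortfall + 1L
        next
      }
      pick <- ok[which.min(abs(cand$gc[ok] - target_gc))]
      used[pick] <- TRUE
      sel <- c(sel, pick)
    }
    if (shortfall > 0) {
      stop(sprintf(
        "insufficient GC-matched peak-free space: %d of %d non-peak windows could not be placed (tolerance %.3f)",
        shortfall, n_nonpeak, tcfg$gc_tol))
    }
    nonpeak <- cand[sel, , drop = FALSE]
  }
  ex <- rbind(
    data.frame(contig = peaks$contig, center = centers, is_peak = TRUE,
               gc = gc_peak, total_counts = counts,
               stringsAsFactors = FALSE),
    if (nrow(nonpeak)) {
      data.frame(contig = nonpeak$contig, center = nonpeak$center,
                 is_peak = FALSE, gc = nonpeak$gc,
                 total_counts = vapply(seq_len(nrow(nonpeak)), function(i) {
                   .window_counts(tracks[[nonpeak$contig[i]]],
                                  nonpeak$center[i], config$output_length)
                 }, numeric(1)), stringsAsFactors = FALSE)
    })
  ex$fold_key <- ex$contig
  rownames(ex) <- NULL
  structure(list(examples = ex, genomes = genomes, tracks = tracks,
                 control_tracks = control_tracks, config = config),
            class = "training_set")
}

#' Materialize one training example
#'
#' Extracts the one-hot input window and the two-strand 5'-end target
#' profile for example `i` of a training set, optionally shifted by
#' `jitter` bases and/or reverse-complemented (which swaps strands and
#' reverses the profile). Targets use `log1p` of window counts for the
#' counts head so empty windows stay finite.
#'
#' @param tset a `training_set`.
#' @param i example index.
#' @param jitter shift in bases.
#' @param rc whether to reverse-complement.
#' @return list with `x` (4 x input_length), `target` (2 x output_length),
#'   `target_log_total`, `ctrl_profile`, `ctrl_logtot`, `fold_key`.
#' @export
materialize_example <- function(tset, i, jitter = 0L, rc = FALSE) {
  cfg <- tset$config
  ex <- tset$examples[i, ]
  g <- tset$genomes[[ex$contig]]
  tr <- tset$tracks[[ex$contig]]
  center <- mod_pos(ex$center + jitter, g$length)
  x <- one_hot(subseq_circular(g, center - cfg$input_length %/% 2L,
                               cfg$input_length))
  oidx <- circ_index(center - cfg$output_length %/% 2L, cfg$output_length,
                     g$length)
  target <- rbind(tr$plus[oidx], tr$minus[oidx])
  ctrl <- tset$control_tracks[[ex$contig]]
  if (!is.null(ctrl) && cfg$use_control) {
    cp <- rbind(ctrl$plus[oidx], ctrl$minus[oidx])
    clt <- log1p(sum(cp))
  } else {
    cp <- matrix(0, 2, cfg$output_length)
    clt <- 0
  }
  if (rc) {
    x <- .rc_onehot(x)
    target <- .rc_profile(target)
    cp <- .rc_profile(cp)
  }
  list(x = x, target = target, target_log_total = log1p(sum(target)),
       ctrl_profile = cp, ctrl_logtot = clt, fold_key = ex$fold_key)
}

#' Assign contigs to cross-validation folds
#'
#' @param fold_keys character vector of per-example contig labels.
#' @param n_folds number of folds.
#' @return named integer vector: fold per distinct contig (round-robin over
#'   sorted contigs).
#' @export
assign_folds <- function(fold_keys, n_folds) {
  contigs <- sort(unique(fold_keys))
  if (length(contigs) < 2 && n_folds > 1) {
    stop("cross-validation by contig needs >= 2 contigs; simulate a multi-contig genome or set n_folds = 1")
  }
  stats::setNames(((seq_along(contigs) - 1L) %% n_folds) + 1L, contigs)
}

## total loss + grads for one example
.example_pass <- function(params, cfg, ex, counts_loss_weight) {
  fw <- nn_forward(params, cfg, ex$x, ex$ctrl_profile, ex$ctrl_logtot)
  nll <- multinomial_profile_nll(fw$logits, ex$target)
  mse <- (fw$log_total - ex$target_log_total)^2
  dlogits <- .profile_nll_grad(fw$logits, ex$target)
  dlt <- 2 * counts_loss_weight * (fw$log_total - ex$target_log_total)
  grads <- nn_backward(params, cfg, fw$cache, dlogits, dlt)
  list(loss = nll + counts_loss_weight * mse, nll = nll, mse = mse,
       grads = grads)
}

.example_loss <- function(params, cfg, ex, counts_loss_weight) {
  fw <- nn_forward(params, cfg, ex$x, ex$ctrl_profile, ex$ctrl_logtot)
  nll <- multinomial_profile_nll(fw$logits, ex$target)
  nll + counts_loss_weight * (fw$log_total - ex$target_log_total)^2
}

#' Train profile models with contig-grouped cross-validation
#'
#' Contigs are partitioned into `n_folds` folds; for each requested fold the
#' fold's contigs form the test set, the next fold the validation set and
#' the rest the training set, so no window ever crosses sets. The loss is
#' the multinomial profile NLL plus `counts_loss_weight` times the counts
#' MSE, minimized by an adaptive-moment optimizer with early stopping on
#' validation loss. Each epoch re-draws jitter for peak windows; with
#' `rc_augment` every window also contributes its reverse complement. A
#' per-fold quality verdict (`usable`) compares held-out profile NLL to the
#' analytic uniform baseline `total_counts * log(2 * output_length)`:
#' models that cannot beat a uniform profile are flagged rather than
#' silently producing predictions.
#'
#' @param tset a `training_set` from [make_training_set()].
#' @param tcfg a [training_config()].
#' @param folds_to_run integer vector of fold indices to train (default all;
#'   scale down for quick runs).
#' @return an object of class `trained_model_cv`: per-fold `profile_model`s,
#'   loss curves, held-out NLL vs baseline and `usable` verdicts.
#' @export
train_profile_model <- function(tset, tcfg = training_config(),
                                folds_to_run = NULL) {
  cfg <- tset$config
  ex_df <- tset$examples
  if (nrow(ex_df) == 0) stop("empty training set")
  folds <- assign_folds(ex_df$fold_key, tcfg$n_folds)
  if (is.null(folds_to_run)) folds_to_run <- sort(unique(folds))
  fits <- list()
  for (f in folds_to_run) {
    if (tcfg$n_folds == 1L) {
      ## no held-out structure: train, validate and test on everything
      train_idx <- val_idx <- test_idx <- seq_len(nrow(ex_df))
      test_contigs <- val_contigs <- names(folds)
    } else {
      test_contigs <- names(folds)[folds == f]
      val_fold <- (f %% max(folds)) + 1L
      val_contigs <- names(folds)[folds == val_fold]
      train_idx <- which(!(ex_df$fold_key %in% c(test_contigs, val_contigs)))
      val_idx <- which(ex_df$fold_key %in% setdiff(val_contigs, test_contigs))
      if (length(val_idx) == 0) val_idx <- which(ex_df$fold_key %in% val_contigs)
      test_idx <- which(ex_df$fold_key %in% test_contigs)
      if (length(train_idx) == 0) stop("fold leaves no training contigs")
    }
    model <- build_model(cfg, seed = tcfg$seed + f)
    theta <- nn_flatten(model$params)
    ast <- adam_init(length(theta))
    val_ex <- lapply(val_idx, function(i) materialize_example(tset, i))
    best <- list(theta = theta, val = Inf, epoch = 0L)
    curve <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
    wait <- 0L
    with_seed(tcfg$seed * 1000L + f, {
      for (epoch in seq_len(tcfg$epochs)) {
        ord <- sample(train_idx)
        jit <- sample(-tcfg$jitter_max:tcfg$jitter_max, length(ord),
                      replace = TRUE)
        jit[!ex_df$is_peak[ord]] <- 0L
        batch_losses <- numeric(0)
        bsz <- tcfg$batch_size
        params <- nn_unflatten(theta, model$params)
        for (bstart in seq(1L, length(ord), by = bsz)) {
          bidx <- bstart:min(length(ord), bstart + bsz - 1L)
          gsum <- NULL
          lsum <- 0
          nex <- 0L
          for (bi in seq_along(bidx)) {
            i <- ord[bidx[bi]]
            variants <- list(materialize_example(tset, i, jit[bidx[bi]],
                                                 rc = FALSE))
            if (tcfg$rc_augment) {
              variants[[2]] <- materialize_example(tset, i, jit[bidx[bi]],
                                                   rc = TRUE)
            }
            for (exm in variants) {
              pass <- .example_pass(params, cfg, exm,
                                    cfg$counts_loss_weight)
              gflat <- nn_flatten(pass$grads)
              gsum <- if (is.null(gsum)) gflat else gsum + gflat
              lsum <- lsum + pass$loss
              nex <- nex + 1L
            }
          }
          upd <- adam_step(theta, gsum / nex, ast, lr = tcfg$lr)
          theta <- upd$theta
          ast <- upd$state
          params <- nn_unflatten(theta, model$params)
          batch_losses <- c(batch_losses, lsum / nex)
        }
        vloss <- mean(vapply(val_ex, function(e)
          .example_loss(params, cfg, e, cfg$counts_loss_weight), numeric(1)))
        curve <- rbind(curve, data.frame(epoch = epoch,
                                         train = mean(batch_losses),
                                         val = vloss))
        if (vloss < best$val - 1e-9) {
          best <- list(theta = theta, val = vloss, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= tcfg$patience) break
        }
      }
    })
    model$params <- nn_unflatten(best$theta, model$params)
    model$trained <- TRUE
    ## held-out quality: profile NLL vs analytic uniform baseline
    test_ex <- lapply(test_idx, function(i) materialize_example(tset, i))
    nll_held <- sum(vapply(test_ex, function(e) {
      fw <- nn_forward(model$params, cfg, e$x, e$ctrl_profile, e$ctrl_logtot)
      multinomial_profile_nll(fw$logits, e$target)
    }, numeric(1)))
    nll_unif <- sum(vapply(test_ex, function(e) {
      sum(e$target) * log(2 * cfg$output_length)
    }, numeric(1)))
    fits[[as.character(f)]] <- list(
      fold = f, model = model, curve = curve,
      test_contigs = test_contigs, val_contigs = val_contigs,
      heldout_nll = nll_held, uniform_nll = nll_unif,
      usable = nll_held < nll_unif)
  }
  structure(list(fits = fits, config = cfg, tcfg = tcfg,
                 folds = folds),
            class = "trained_model_cv")
}

#' Predict expected per-base profiles over the whole circular genome
#'
#' The genome is split into `output_length` tiles around the circle (the
#' last tile wraps); each tile's input window is the `input_length`
#' circular context centered on it. Per-window predictions average the
#' forward and reverse-complement passes; per-base expected counts are the
#' softmax profile probability times `exp(predicted log total)`. Bases
#' covered by more than one tile (wrap overlap) are averaged, as are
#' predictions from multiple fold models, so every base receives exactly
#' one stitched value.
#'
#' @param models a `profile_model`, a `trained_model_cv`, or a list of
#'   `profile_model`s.
#' @param genome a [circular_genome()].
#' @param control_track optional control 5'-end [stranded_track()]; by
#'   default the control input is the genome-wide mean control profile (or
#'   zeros with `zero_control = TRUE` / when absent).
#' @param offset tile origin, bases (exposed for equivariance testing).
#' @param zero_control force zero control input.
#' @return a [stranded_track()] of kind `"predicted"` with a `provenance`
#'   attribute.
#' @export
predict_circular <- function(models, genome, control_track = NULL,
                             offset = 0L, zero_control = FALSE) {
  if (inherits(models, "trained_model_cv")) {
    usable <- Filter(function(f) f$usable, models$fits)
    if (length(usable) == 0) {
      warning("no usable fold models; predicting with all folds")
      usable <- models$fits
    }
    models <- lapply(usable, `[[`, "model")
  }
  if (inherits(models, "profile_model")) models <- list(models)
  for (m in models) {
    if (!m$trained) stop("predict_circular requires trained model(s)")
  }
  cfg <- models[[1]]$config
  len <- genome$length
  if (len < cfg$output_length) stop("genome shorter than output window")
  n_tiles <- ceiling(len / cfg$output_length)
  sum_p <- matrix(0, 2, len)
  n_p <- numeric(len)
  flank <- (cfg$input_length - cfg$output_length) %/% 2L
  ctrl_mean <- NULL
  if (!is.null(control_track) && !zero_control && cfg$use_control) {
    ctrl_mean <- c(mean(control_track$plus), mean(control_track$minus))
  }
  for (t in seq_len(n_tiles) - 1L) {
    s <- mod_pos(offset + t * cfg$output_length, len)
    x <- one_hot(subseq_circular(genome, s - flank, cfg$input_length))
    if (!is.null(control_track) && !zero_control && cfg$use_control) {
      oidx <- circ_index(s, cfg$output_length, len)
      cp <- rbind(control_track$plus[oidx], control_track$minus[oidx])
      clt <- log1p(sum(cp))
    } else {
      cp <- matrix(0, 2, cfg$output_length)
      clt <- 0
    }
    tile_pred <- matrix(0, 2, cfg$output_length)
    for (m in models) {
      fw <- nn_forward(m$params, cfg, x, cp, clt)
      z <- as.numeric(fw$logits)
      z <- z - max(z)
      p_f <- matrix(exp(z) / sum(exp(z)), 2)
      fw_rc <- nn_forward(m$params, cfg, .rc_onehot(x), .rc_profile(cp), clt)
      zr <- as.numeric(fw_rc$logits)
      zr <- zr - max(zr)
      p_r <- .rc_profile(matrix(exp(zr) / sum(exp(zr)), 2))
      prob <- (p_f + p_r) / 2
      tot <- exp((fw$log_total + fw_rc$log_total) / 2)
      tile_pred <- tile_pred + prob * tot
    }
    tile_pred <- tile_pred / length(models)
    oidx <- circ_index(s, cfg$output_length, len)
    sum_p[, oidx] <- sum_p[, oidx] + tile_pred
    n_p[oidx] <- n_p[oidx] + 1
  }
  if (any(n_p == 0)) stop("internal error: tiling left uncovered bases")
  pred <- sweep(sum_p, 2, n_p, "/")
  tr <- stranded_track(genome$name, "predicted", pred[1, ], pred[2, ])
  attr(tr, "provenance") <- list(n_models = length(models),
                                 n_tiles = n_tiles, offset = offset,
                                 input_length = cfg$input_length,
                                 output_length = cfg$output_length)
  tr
}

#' Peaks of a predicted track
#'
#' Local maxima of the smoothed total predicted signal above a quantile
#' threshold.
#'
#' @param predicted a `"predicted"` [stranded_track()].
#' @param quantile_threshold signal quantile a peak must exceed.
#' @param min_separation minimum distance between reported peaks, bases.
#' @param smooth_window smoothing window, bases.
#' @return integer vector of 0-based peak positions.
#' @export
predicted_peaks <- function(predicted, quantile_threshold = 0.95,
                            min_separation = 150, smooth_window = 15) {
  total <- circ_smooth(predicted$plus + predicted$minus, smooth_window)
  len <- length(total)
  thr <- stats::quantile(total, quantile_threshold, names = FALSE)
  ord <- order(total, decreasing = TRUE)
  peaks <- integer(0)
  for (p in ord) {
    ## strictly above the threshold: a flat track has no peaks
    if (total[p] <= thr) break
    if (length(peaks) == 0 ||
        all(circ_dist(p - 1L, peaks, len) >= min_separation)) {
      peaks <- c(peaks, p - 1L)
    }
  }
  sort(peaks)
}

#' Fraction of observed calls corroborated by model predictions
#'
#' An observed `occupancy_like` call is corroborated when its estimated
#' binding position lies within `d_max` of a predicted peak. Predicted
#' peaks with no observed counterpart do not penalize the score (models
#' routinely predict occupancy at motifs that are not bound in the assayed
#' context).
#'
#' @param calls list of `peak_call`s (or a [screen_dataset()] result).
#' @param predicted a `"predicted"` [stranded_track()].
#' @param d_max maximum distance, bases.
#' @param quantile_threshold passed to [predicted_peaks()].
#' @return list with `score` (fraction, NA when there are no occupancy
#'   calls), `flags` (per occupancy call), `predicted_peaks`.
#' @export
corroboration_score <- function(calls, predicted, d_max = 100,
                                quantile_threshold = 0.95) {
  if (!is.null(calls$calls)) calls <- calls$calls
  len <- length(predicted$plus)
  occ <- Filter(function(cl) cl$label == "occupancy_like", calls)
  pp <- predicted_peaks(predicted, quantile_threshold)
  if (length(occ) == 0) {
    return(list(score = NA_real_, flags = logical(0), predicted_peaks = pp,
                defined = FALSE))
  }
  flags <- vapply(occ, function(cl) {
    ctr <- call_center(cl, len)
    length(pp) > 0 && min(circ_dist(ctr, pp, len)) <= d_max
  }, logical(1))
  list(score = mean(flags), flags = flags, predicted_peaks = pp,
       defined = TRUE)
}
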