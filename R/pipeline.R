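#' Default demo run configuration
#'
#' A small synthetic world exercising every stage on one CPU in well under
#' the pipeline budget: a 6 kb circular genome with one planted duplication,
#' five occupancy sites with a planted motif, one D-loop-like symmetric
#' artifact inside a configured mask, a ChIP library and a matched control
#' library.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `run_config`.
#' @export
demo_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    genome = list(length = 6000L, gc_content = 0.44,
                  duplications = list(c(100L, 300L, 3000L))),
    motif = list(consensus = "TTAACGGC",
                 positions = c(800L, 1600L, 2500L, 4200L, 5200L),
                 enrichment = 20),
    artifact = list(position = 300L, enrichment = 20,
                    mask = list(start = 5900L, width = 500L)),
    reads = list(n_reads = 50000L, read_length = 36L,
                 fragment_length_mean = 200, fragment_length_sd = 30,
                 background_fraction = 0.5),
    mappability = list(k = 36L, mismatches = 2L, circular_kmers = TRUE),
    screen = list(),
    run_model = FALSE), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a `run_config` (or a plain list; e.g. from
#'   [jsonlite::read_json()]).
#' @return the validated config, invisibly; referenced paths that do not
#'   exist raise an error before any stage runs.
#' @export
validate_config <- function(config) {
  for (p in c(config$paths$genome, config$paths$alignments,
              config$paths$peaks, config$paths$masks)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("configured path does not exist: %s", p))
    }
  }
  if (is.null(config$seed)) stop("config must carry a seed")
  invisible(config)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> mappability -> tracks -> screen (-> model, when
#' `config$run_model`) in dependency order, writing FASTA, SAM, bedGraph,
#' BED and TSV outputs plus a JSON manifest with the seed, parameters and a
#' checksum for every output file. Re-running with an identical config and
#' seed reproduces identical non-stochastic outputs byte for byte.
#'
#' @param config a `run_config`, see [demo_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the run directory path, invisibly; the manifest is
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = demo_config(), outdir = tempfile("run_"),
                         quiet = FALSE) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), outdir), call. = FALSE)
    })
  }
  seed <- config$seed
  ## --- simulate ---
  say("stage simulate: genome %d bp", config$genome$length)
  world <- stage("simulate", {
    g0 <- generate_circular_genome(config$genome$length,
                                   config$genome$gc_content,
                                   config$genome$duplications, seed = seed)
    pl <- data.frame(position = config$motif$positions, strand = "+",
                     enrichment = config$motif$enrichment,
                     kind = "occupancy")
    pl <- rbind(pl, data.frame(position = config$artifact$position,
                               strand = "both",
                               enrichment = config$artifact$enrichment,
                               kind = "artifact"))
    planted <- plant_motifs(g0, config$motif$consensus, pl)
    cfg <- sim_config(config$reads$n_reads, config$reads$read_length,
                      config$reads$fragment_length_mean,
                      config$reads$fragment_length_sd,
                      config$reads$background_fraction, seed = seed + 1L)
    aset <- simulate_reads(planted$genome, planted$sites, cfg)
    ccfg <- sim_config(config$reads$n_reads, config$reads$read_length,
                       config$reads$fragment_length_mean,
                       config$reads$fragment_length_sd,
                       1, seed = seed + 2L, control = TRUE)
    ctrl <- simulate_reads(planted$genome, planted$sites, ccfg)
    write_genome_fasta(planted$genome, file.path(outdir, "genome.fa"))
    write_truth(planted$sites, file.path(outdir, "truth.bed"),
                planted$genome$name, planted$genome$length)
    write_alignments_sam(aset, planted$genome,
                         file.path(outdir, "chip.sam"))
    write_alignments_sam(ctrl, planted$genome,
                         file.path(outdir, "control.sam"))
    list(genome = planted$genome, sites = planted$sites, aset = aset,
         ctrl = ctrl)
  })
  ## --- mappability ---
  say("stage mappability: k=%d", config$mappability$k)
  mp <- stage("mappability", {
    tr <- compute_mappability(world$genome, k = config$mappability$k,
                              mismatches = config$mappability$mismatches,
                              circular_kmers =
                                isTRUE(config$mappability$circular_kmers))
    write_mappability(tr, file.path(outdir, "mappability.bedGraph"))
    tr
  })
  ## --- tracks ---
  say("stage tracks")
  trk <- stage("tracks", {
    cov <- coverage_track(world$aset, world$genome$length)
    fp <- five_prime_track(world$aset, world$genome$length)
    cfp <- five_prime_track(world$ctrl, world$genome$length)
    write_track(cov, file.path(outdir, "coverage"))
    write_track(fp, file.path(outdir, "five_prime"))
    write_track(cfp, file.path(outdir, "control_five_prime"))
    list(cov = cov, fp = fp, cfp = cfp)
  })
  ## --- screen ---
  say("stage screen")
  masks <- data.frame(start = config$artifact$mask$start,
                      width = config$artifact$mask$width, label = "D-loop")
  scr <- stage("screen", {
    params <- do.call(screen_params, config$screen)
    res <- screen_dataset(world$aset, world$genome, mp, masks, params)
    write_calls_bed(res, file.path(outdir, "calls.bed"),
                    world$genome$name, world$genome$length)
    utils::write.table(res$report, file.path(outdir, "screen_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  ## --- plots ---
  stage("plots", {
    plot_strand_profiles(trk$cov, scr$calls, masks, style = "circular",
                         path = file.path(outdir, "profile_circular.png"))
    plot_strand_profiles(trk$cov, scr$calls, masks, style = "linear",
                         path = file.path(outdir, "profile_linear.png"))
  })
  ## --- optional model stage (scaled-down config) ---
  if (isTRUE(config$run_model)) {
    say("stage model (scaled-down)")
    stage("model", {
      mres <- .demo_model_stage(world, trk, seed, outdir)
      utils::write.table(mres$metrics, file.path(outdir, "model_metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  ## --- manifest ---
  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("mitochip")),
    seed = seed,
    config = config,
    n_reads = nrow(world$aset$reads),
    n_calls = length(scr$calls),
    call_labels = table(vapply(scr$calls, `[[`, character(1), "label")),
    outputs = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(outdir, f))))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  say("run complete: %s", outdir)
  invisible(outdir)
}

## tiny multi-contig model demo used by the optional pipeline model stage
.demo_model_stage <- function(world, trk, seed, outdir) {
  cfg <- profile_model_config(input_length = 514, output_length = 250,
                              n_conv_layers = 4, n_filters = 16,
                              use_control = FALSE)
  sim <- simulate_motif_world(n_contigs = 3, contig_length = 3000,
                              sites_per_contig = 4, n_reads = 15000,
                              seed = seed)
  tset <- make_training_set(sim$peaks, sim$genomes, sim$tracks,
                            config = cfg,
                            tcfg = training_config(n_folds = 3,
                                                   jitter_max = 32,
                                                   seed = seed))
  fit <- train_profile_model(tset, training_config(n_folds = 3,
                                                   jitter_max = 32,
                                                   seed = seed, epochs = 8,
                                                   batch_size = 16,
                                                   patience = 3),
                             folds_to_run = 1L)
  f1 <- fit$fits[[1]]
  pred <- predict_circular(f1$model, sim$genomes[[f1$test_contigs[1]]])
  write_track(pred, file.path(outdir, "predicted"))
  list(metrics = data.frame(fold = f1$fold, heldout_nll = f1$heldout_nll,
                            uniform_nll = f1$uniform_nll,
                            usable = f1$usable))
}

#' Simulate a multi-contig motif world for model training
#'
#' Generates `n_contigs` independent circular contigs, plants the same
#' motif at regularly spaced sites on each, simulates reads and builds
#' 5'-end tracks — the stand-in for a multi-chromosome genome that makes
#' contig-grouped cross-validation possible in an organellar setting.
#'
#' @param n_contigs number of contigs (each becomes one fold key).
#' @param contig_length contig length, bases.
#' @param sites_per_contig planted occupancy sites per contig.
#' @param motif planted consensus.
#' @param enrichment site enrichment weight.
#' @param n_reads reads per contig.
#' @param fragment_length_mean,fragment_length_sd library model. The
#'   default is a short-fragment (80 bp) library: a scaled-down model with
#'   4 layers and a 75-base profile head sees only about +/-60 bases of
#'   sequence per output position, so the strand summits (at +/- half the
#'   fragment length around a motif) must fall inside that receptive field
#'   for sequence-to-profile learning to be expressible at all. Full-size
#'   configurations (receptive field > 1 kb) accommodate conventional
#'   200 bp libraries.
#' @param background_fraction fraction of uniform background reads.
#' @param seed master seed.
#' @return list with `genomes`, `tracks`, `peaks` (data.frame
#'   contig/start/end), `sites` (named list of [truth_sites()]).
#' @export
simulate_motif_world <- function(n_contigs = 5, contig_length = 6000,
                                 sites_per_contig = 10, motif = "TTAACGGC",
                                 enrichment = 30, n_reads = 30000,
                                 fragment_length_mean = 80,
                                 fragment_length_sd = 10,
                                 background_fraction = 0.25, seed = 1) {
  genomes <- list()
  tracks <- list()
  sites <- list()
  peaks <- NULL
  for (ci in seq_len(n_contigs)) {
    nm <- sprintf("contig%02d", ci)
    g0 <- generate_circular_genome(contig_length, 0.44, seed = seed * 100 + ci,
                                   name = nm)
    pos <- round(seq(contig_length / (2 * sites_per_contig),
                     contig_length * (1 - 1 / (2 * sites_per_contig)),
                     length.out = sites_per_contig))
    pl <- data.frame(position = pos, strand = "+", enrichment = enrichment,
                     kind = "occupancy")
    planted <- plant_motifs(g0, motif, pl)
    cfg <- sim_config(n_reads, fragment_length_mean = fragment_length_mean,
                      fragment_length_sd = fragment_length_sd,
                      background_fraction = background_fraction,
                      seed = seed * 100 + ci + 50L)
    aset <- simulate_reads(planted$genome, planted$sites, cfg)
    genomes[[nm]] <- planted$genome
    tracks[[nm]] <- five_prime_track(aset, contig_length)
    sites[[nm]] <- planted$sites
    peaks <- rbind(peaks, data.frame(contig = nm, start = pos - 100L,
                                     end = pos + 100L,
                                     stringsAsFactors = FALSE))
  }
  list(genomes = genomes, tracks = tracks, peaks = peaks, sites = sites)
}

#' Plot plus/minus strand profiles
#'
#' Circular style renders the two strands as opposing rings (plus outward
#' in black, minus inward in yellow-orange, the conventional coloring) with
#' an annotation band for masks and markers at calls; linear style renders
#' mirrored strand tracks. Rendering is deterministic.
#'
#' @param track a [stranded_track()] (observed); optionally a list whose
#'   first element is observed and second a predicted overlay.
#' @param calls optional list of `peak_call`s (or [screen_dataset()]
#'   result); occupancy-like and artifact-like calls are drawn distinctly.
#' @param masks optional mask data.frame (`start`, `width`).
#' @param style `"circular"` or `"linear"`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_strand_profiles <- function(track, calls = NULL, masks = NULL,
                                 style = c("circular", "linear"),
                                 path = "profile.png") {
  style <- match.arg(style)
  tracks <- if (inherits(track, "stranded_track")) list(track) else track
  if (length(tracks) == 0) stop("empty track set")
  if (!is.null(calls$calls)) calls <- calls$calls
  obs <- tracks[[1]]
  len <- length(obs$plus)
  grDevices::png(path, width = 900, height = 900, res = 110)
  on.exit(grDevices::dev.off())
  norm <- function(v) if (max(v) > 0) v / max(v) else v
  lab_col <- function(lb) switch(lb, occupancy_like = "firebrick",
                                 artifact_like = "grey40",
                                 masked = "steelblue", "orange3")
  if (style == "circular") {
    theta <- 2 * pi * (seq_len(len) - 1L) / len
    graphics::par(mar = c(1, 1, 2, 1))
    graphics::plot(NA, xlim = c(-1.6, 1.6), ylim = c(-1.6, 1.6), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s strand profiles", obs$genome_name))
    r0 <- 1
    graphics::lines(r0 * cos(theta), r0 * sin(theta), col = "grey70")
    rp <- r0 + 0.45 * norm(circ_smooth(obs$plus, 15))
    rm <- r0 - 0.45 * norm(circ_smooth(obs$minus, 15))
    graphics::lines(rp * cos(theta), rp * sin(theta), col = "black")
    graphics::lines(rm * cos(theta), rm * sin(theta), col = "darkgoldenrod2")
    if (length(tracks) > 1) {
      pr <- r0 + 0.45 * norm(circ_smooth(tracks[[2]]$plus +
                                           tracks[[2]]$minus, 15))
      graphics::lines(pr * cos(theta), pr * sin(theta), col = "dodgerblue",
                      lty = 2)
    }
    for (i in seq_len(NROW(masks))) {
      idx <- circ_index(masks$start[i], masks$width[i], len)
      graphics::lines(0.5 * cos(theta[idx]), 0.5 * sin(theta[idx]),
                      col = "steelblue", lwd = 4)
    }
    for (cl in calls) {
      ctr <- call_center(cl, len) + 1L
      graphics::points(1.55 * cos(theta[ctr]), 1.55 * sin(theta[ctr]),
                       pch = 19, col = lab_col(cl$label))
    }
    graphics::legend("center", bty = "n", cex = 0.8,
                     legend = c("plus", "minus", "occupancy_like",
                                "artifact_like", "masked"),
                     col = c("black", "darkgoldenrod2", "firebrick",
                             "grey40", "steelblue"),
                     lty = c(1, 1, NA, NA, NA), pch = c(NA, NA, 19, 19, 19))
  } else {
    graphics::par(mar = c(4, 4, 2, 1))
    up <- circ_smooth(obs$plus, 15)
    dn <- circ_smooth(obs$minus, 15)
    graphics::plot(NA, xlim = c(0, len), ylim = c(-max(dn, 1), max(up, 1)),
                   xlab = sprintf("%s position (bp)", obs$genome_name),
                   ylab = "coverage (minus mirrored)",
                   main = "strand profiles")
    graphics::lines(seq_len(len) - 1L, up, col = "black")
    graphics::lines(seq_len(len) - 1L, -dn, col = "darkgoldenrod2")
    for (i in seq_len(NROW(masks))) {
      graphics::rect(masks$start[i], -max(dn) * 0.05,
                     masks$start[i] + masks$width[i], max(up) * 0.05,
                     col = grDevices::adjustcolor("steelblue", 0.4),
                     border = NA)
    }
    for (cl in calls) {
      ctr <- call_center(cl, len)
      graphics::abline(v = ctr, col = lab_col(cl$label), lty = 3)
    }
  }
  invisible(path)
}
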