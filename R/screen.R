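#' Screening parameters
#'
#' Knobs for the asymmetry-based occupancy screen. The screen
#' operationalizes visual inspection of circular strand-coverage plots: true
#' punctate occupancy shows plus/minus 5'-end summits separated by the
#' library fragment length, while D-loop-like artifacts are strand
#' symmetric. None of these thresholds are literature values; they are
#' explicit, reported knobs.
#'
#' @param fold_min minimum peak fold over the background (median coverage
#'   over mappable, unmasked bases) for a candidate region.
#' @param w_min minimum candidate width in bases.
#' @param g_max sub-threshold gaps up to this size are merged. The default
#'   (150) is chosen to bridge the low-coverage valley between a site's two
#'   strand humps, whose width is about `fragment_length - 2 * read_length`
#'   (~130 bp for a 200 bp library of 36-mers); a smaller gap bisects every
#'   genuine site into two half-candidates.
#' @param smooth_window moving-average window (bases) applied before
#'   thresholding and before cross-correlation.
#' @param max_lag maximum strand lag scanned, bases.
#' @param lag_min,lag_max acceptable best-lag window for an occupancy call
#'   (brackets plausible ChIP fragment lengths).
#' @param score_min minimum asymmetry score (best-lag correlation gain over
#'   lag 0).
#' @param mask_overlap_max a region overlapping a configured artifact mask
#'   by more than this fraction of its width is labelled `masked`.
#' @return a list of class `screen_params`.
#' @export
screen_params <- function(fold_min = 3, w_min = 25, g_max = 150,
                          smooth_window = 15, max_lag = 500, lag_min = 50,
                          lag_max = 400, score_min = 0.3,
                          mask_overlap_max = 0.5) {
  structure(list(fold_min = fold_min, w_min = w_min, g_max = g_max,
                 smooth_window = smooth_window, max_lag = max_lag,
                 lag_min = lag_min, lag_max = lag_max, score_min = score_min,
                 mask_overlap_max = mask_overlap_max),
            class = "screen_params")
}

## Candidate region: modular half-open interval carried as (start, width),
## start in [0, L); end = start + width may exceed L for wrap-spanning runs.
.candidate_region <- function(start, width, fold, summit_plus, summit_minus) {
  list(start = start, width = width, end = start + width, fold = fold,
       summit_plus = summit_plus, summit_minus = summit_minus)
}

#' Call candidate enriched regions on the circle
#'
#' Background is the median of total (plus + minus) coverage over mappable,
#' unmasked bases (floored at 1 count when zero with nonzero signal).
#' Candidates are maximal circular runs where the smoothed total coverage
#' reaches `fold_min` times background; runs separated by gaps up to
#' `g_max` are merged, and runs narrower than `w_min` are dropped. A run
#' spanning the origin yields one modular candidate, not two.
#'
#' @param track a [stranded_track()] of kind `"coverage"`.
#' @param mappability optional `mappability_track` of matching length.
#' @param params a [screen_params()].
#' @param masks optional data.frame of artifact mask intervals (`start`,
#'   `width`), excluded from background estimation.
#' @return list of candidate regions (fields `start`, `width`, `end`,
#'   `fold`, `summit_plus`, `summit_minus`).
#' @export
call_candidates <- function(track, mappability = NULL,
                            params = screen_params(), masks = NULL) {
  len <- length(track$plus)
  total <- track$plus + track$minus
  if (!is.null(mappability) && length(mappability$values) != len) {
    stop("track and mappability track lengths differ")
  }
  bg_ok <- rep(TRUE, len)
  if (!is.null(mappability)) bg_ok <- bg_ok & (mappability$values == 1)
  for (i in seq_len(NROW(masks))) {
    bg_ok[circ_index(masks$start[i], masks$width[i], len)] <- FALSE
  }
  if (all(total == 0)) {
    message("all-zero coverage track: no candidates")
    return(list())
  }
  bg <- stats::median(total[bg_ok])
  if (bg == 0) {
    message("zero background with nonzero peaks: background floored at 1")
    bg <- 1
  }
  sm <- circ_smooth(total, params$smooth_window)
  smp <- circ_smooth(track$plus, params$smooth_window)
  smm <- circ_smooth(track$minus, params$smooth_window)
  above <- sm >= params$fold_min * bg
  if (!any(above)) return(list())
  ## circular run detection: rotate so position 0 is below threshold
  if (all(above)) {
    runs <- data.frame(start = 0L, width = len)
  } else {
    r0 <- which(!above)[1] - 1L
    av <- rotate_vec(above, r0)
    rl <- rle(av)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths
    runs <- data.frame(start = mod_pos(starts[rl$values] + r0, len),
                       width = rl$lengths[rl$values])
    ## merge runs separated by gaps <= g_max (in rotated order runs are
    ## sorted and non-wrapping except via the rotation offset)
    if (nrow(runs) > 1) {
      rs <- starts[rl$values]  # rotated starts, ascending
      rw <- rl$lengths[rl$values]
      merged <- list(c(rs[1], rw[1]))
      for (i in seq_len(nrow(runs))[-1]) {
        last <- merged[[length(merged)]]
        gap <- rs[i] - (last[1] + last[2])
        if (gap <= params$g_max) {
          merged[[length(merged)]] <- c(last[1], rs[i] + rw[i] - last[1])
        } else {
          merged[[length(merged) + 1L]] <- c(rs[i], rw[i])
        }
      }
      ## wrap gap between last merged run and first (across the rotation)
      if (length(merged) > 1) {
        first <- merged[[1]]
        last <- merged[[length(merged)]]
        if ((len - (last[1] + last[2])) + first[1] <= params$g_max) {
          merged[[1]] <- c(last[1], first[1] + first[2] + (len - last[1]))
          merged[[length(merged)]] <- NULL
        }
      }
      runs <- data.frame(start = mod_pos(vapply(merged, `[`, 0, 1) + r0, len),
                         width = vapply(merged, `[`, 0, 2))
    }
  }
  runs <- runs[runs$width >= params$w_min, , drop = FALSE]
  out <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- circ_index(runs$start[i], runs$width[i], len)
    pos0 <- mod_pos(seq.int(runs$start[i], length.out = runs$width[i]), len)
    .candidate_region(runs$start[i], runs$width[i],
                      fold = max(sm[idx]) / bg,
                      summit_plus = pos0[which.max(smp[idx])],
                      summit_minus = pos0[which.max(smm[idx])])
  })
  out
}

#' Strand-asymmetry statistic for a candidate region
#'
#' Correlates the smoothed plus-strand 5' profile with the minus-strand
#' profile shifted left by each lag in `[0, max_lag]`, over the region
#' padded by `max_lag` on both sides (circularly). True occupancy maximizes
#' the correlation near the fragment length; symmetric artifacts peak at
#' lag 0. The score is the correlation gain of the best lag over lag 0.
#'
#' @param track a [stranded_track()] of kind `"five_prime"`.
#' @param region a candidate region from [call_candidates()].
#' @param max_lag maximum lag scanned (must be < genome length / 2).
#' @param smooth_window smoothing window, bases.
#' @return a list of class `asymmetry_result` with `best_lag`, `corr_best`,
#'   `corr_zero`, `score`, `defined`. Regions with no reads on either strand
#'   give `defined = FALSE` and NA correlations.
#' @export
asymmetry <- function(track, region, max_lag = 500, smooth_window = 15) {
  len <- length(track$plus)
  if (max_lag >= len / 2) stop("max_lag must be < genome length / 2")
  idx <- circ_index(region$start - max_lag, region$width + 2L * max_lag, len)
  p <- track$plus[idx]
  m <- track$minus[idx]
  res <- list(best_lag = NA_integer_, corr_best = NA_real_,
              corr_zero = NA_real_, score = NA_real_, defined = FALSE)
  class(res) <- "asymmetry_result"
  if (sum(p) == 0 || sum(m) == 0) return(res)
  p <- circ_smooth(p, smooth_window)
  m <- circ_smooth(m, smooth_window)
  n <- length(p)
  cors <- vapply(0:max_lag, function(lag) {
    a <- p[seq_len(n - lag)]
    b <- m[seq_len(n - lag) + lag]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (all(is.na(cors))) return(res)
  best <- which.max(cors)  # first maximum: smallest lag wins ties
  res$best_lag <- best - 1L
  res$corr_best <- cors[best]
  res$corr_zero <- cors[1]
  res$score <- res$corr_best - res$corr_zero
  res$defined <- TRUE
  res
}

## overlap fraction of a modular region with mask intervals
.mask_overlap <- function(region, masks, len) {
  if (is.null(masks) || NROW(masks) == 0) return(0)
  pos <- mod_pos(seq.int(region$start, length.out = region$width), len)
  inmask <- rep(FALSE, length(pos))
  for (i in seq_len(NROW(masks))) {
    mpos <- mod_pos(seq.int(masks$start[i], length.out = masks$width[i]), len)
    inmask <- inmask | (pos %in% mpos)
  }
  mean(inmask)
}

#' Classify a candidate region
#'
#' Applies the screen's decision rule: `masked` when the region overlaps a
#' configured artifact mask (e.g. the D-loop/control region) beyond the
#' overlap threshold, regardless of score; `occupancy_like` when the best
#' lag falls in `[lag_min, lag_max]` and the asymmetry score reaches
#' `score_min`; `artifact_like` when the profile is strand-symmetric (best
#' lag below `lag_min` or score below `score_min`); otherwise `ambiguous`
#' (including undefined asymmetry).
#'
#' @param region a candidate region.
#' @param asym an `asymmetry_result` for that region.
#' @param masks optional data.frame of mask intervals (`start`, `width`,
#'   optional `label`).
#' @param params a [screen_params()].
#' @param mappability optional `mappability_track` used to annotate the
#'   mappable fraction (regions below 0.5 are flagged, not discarded:
#'   organellar peaks dwarf nuclear-repeat artifacts).
#' @param genome_length genome length in bases.
#' @return a list of class `peak_call` with fields `region`, `asymmetry`,
#'   `label`, `mappable_fraction`.
#' @export
classify <- function(region, asym, masks = NULL, params = screen_params(),
                     mappability = NULL, genome_length) {
  mf <- if (is.null(mappability)) NA_real_ else {
    mean(mappability$values[circ_index(region$start, region$width,
                                       genome_length)])
  }
  ov <- .mask_overlap(region, masks, genome_length)
  label <- if (ov > params$mask_overlap_max) {
    "masked"
  } else if (!isTRUE(asym$defined)) {
    "ambiguous"
  } else if (asym$best_lag >= params$lag_min &&
             asym$best_lag <= params$lag_max &&
             asym$score >= params$score_min) {
    "occupancy_like"
  } else if (asym$best_lag < params$lag_min || asym$score < params$score_min) {
    "artifact_like"
  } else {
    "ambiguous"
  }
  structure(list(region = region, asymmetry = asym, label = label,
                 mappable_fraction = mf),
            class = "peak_call")
}

#' Estimated binding position of a peak call
#'
#' Midpoint (on the circle) between the plus- and minus-strand summits; for
#' a genuine site this estimates the fragment midpoint, i.e. the site
#' itself.
#'
#' @param call a `peak_call`.
#' @param genome_length genome length.
#' @return 0-based position.
#' @export
call_center <- function(call, genome_length) {
  sp <- call$region$summit_plus
  sm <- call$region$summit_minus
  d <- mod_pos(sm - sp, genome_length)
  if (d <= genome_length - d) {
    mod_pos(sp + d %/% 2L, genome_length)
  } else {
    mod_pos(sm + (genome_length - d) %/% 2L, genome_length)
  }
}

#' Run the full occupancy screen on one dataset
#'
#' Pipeline: load (if given a path) -> coverage and 5'-end tracks ->
#' candidate regions -> per-region strand asymmetry -> classification.
#'
#' @param alignments an [alignment_set()] or a SAM/BAM path.
#' @param genome a [circular_genome()].
#' @param mappability optional `mappability_track`.
#' @param masks optional data.frame of artifact mask intervals (`start`,
#'   `width`, optional `label`), e.g. the D-loop/control region.
#' @param params a [screen_params()].
#' @param paired passed to [load_alignments()] when `alignments` is a path.
#' @return list with `calls` (list of `peak_call`), `report` (one row per
#'   call), and the computed `coverage`/`five_prime` tracks.
#' @export
screen_dataset <- function(alignments, genome, mappability = NULL,
                           masks = NULL, params = screen_params(),
                           paired = FALSE) {
  aset <- if (is.character(alignments)) {
    load_alignments(alignments, genome$name, paired = paired)
  } else alignments
  cov <- coverage_track(aset, genome$length)
  fp <- five_prime_track(aset, genome$length)
  cands <- call_candidates(cov, mappability, params, masks)
  calls <- lapply(cands, function(rg) {
    a <- asymmetry(fp, rg, max_lag = params$max_lag,
                   smooth_window = params$smooth_window)
    classify(rg, a, masks, params, mappability, genome$length)
  })
  report <- if (length(calls)) {
    do.call(rbind, lapply(calls, function(cl) {
      data.frame(start = cl$region$start,
                 end = mod_pos(cl$region$end - 1L, genome$length) + 1L,
                 width = cl$region$width, fold = cl$region$fold,
                 summit_plus = cl$region$summit_plus,
                 summit_minus = cl$region$summit_minus,
                 center = call_center(cl, genome$length),
                 best_lag = cl$asymmetry$best_lag,
                 corr_best = cl$asymmetry$corr_best,
                 corr_zero = cl$asymmetry$corr_zero,
                 score = cl$asymmetry$score, label = cl$label,
                 mappable_fraction = cl$mappable_fraction,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(start = integer(0), end = integer(0), width = integer(0),
               fold = numeric(0), summit_plus = integer(0),
               summit_minus = integer(0), center = integer(0),
               best_lag = integer(0), corr_best = numeric(0),
               corr_zero = numeric(0), score = numeric(0),
               label = character(0), mappable_fraction = numeric(0))
  }
  list(calls = calls, report = report, coverage = cov, five_prime = fp,
       n_reads = nrow(aset$reads))
}

#' Write screen calls as BED
#'
#' Wrap-spanning calls are split into two lines sharing a name; label and
#' asymmetry score ride in columns 4 and 5 side-fields.
#'
#' @param calls list of `peak_call` (or a `screen_dataset()` result).
#' @param path output path.
#' @param genome_name,genome_length contig name and length.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path, genome_name, genome_length) {
  if (!is.null(calls$calls)) calls <- calls$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\tlabel\tbest_lag\tfold",
             con)
  for (i in seq_along(calls)) {
    cl <- calls[[i]]
    s <- cl$region$start
    e <- cl$region$end
    seg <- if (e <= genome_length) cbind(s, e) else {
      rbind(c(s, genome_length), c(0L, e - genome_length))
    }
    for (j in seq_len(nrow(seg))) {
      writeLines(sprintf("%s\t%d\t%d\tcall%03d\t%s\t.\t%s\t%s\t%.3f",
                         genome_name, seg[j, 1], seg[j, 2], i,
                         ifelse(is.na(cl$asymmetry$score), "0",
                                sprintf("%.3f", cl$asymmetry$score)),
                         cl$label,
                         ifelse(is.na(cl$asymmetry$best_lag), ".",
                                as.character(cl$asymmetry$best_lag)),
                         cl$region$fold), con)
    }
  }
  invisible(path)
}
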