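#' Per-dataset screening record
#'
#' Bundles one dataset's screen results with the metadata needed for
#' orthogonal-evidence tiering: the assayed target, the cell context and
#' the immuno-reagent identity (a specific antibody, optionally
#' lot-resolved, or an endogenous epitope tag).
#'
#' @param dataset_id unique dataset identifier.
#' @param target protein name.
#' @param cell_context cell line / tissue label.
#' @param reagent_class `"antibody"` or `"epitope_tag"`.
#' @param reagent_id reagent identifier (antibody catalog id, tag name).
#' @param lot optional reagent lot.
#' @param production_group optional producing lab.
#' @param calls list of `peak_call`s (or a [screen_dataset()] result).
#' @param corroboration optional [corroboration_score()] fraction.
#' @return a list of class `dataset_record`.
#' @export
dataset_record <- function(dataset_id, target, cell_context = NA_character_,
                           reagent_class = c("antibody", "epitope_tag"),
                           reagent_id, lot = NA_character_,
                           production_group = NA_character_, calls = list(),
                           corroboration = NA_real_) {
  reagent_class <- match.arg(reagent_class)
  if (!is.null(calls$calls)) calls <- calls$calls
  structure(list(dataset_id = as.character(dataset_id),
                 target = as.character(target),
                 cell_context = as.character(cell_context),
                 reagent_class = reagent_class,
                 reagent_id = as.character(reagent_id),
                 lot = as.character(lot),
                 production_group = as.character(production_group),
                 calls = calls, corroboration = corroboration),
            class = "dataset_record")
}

.occupancy_centers <- function(calls, len) {
  occ <- Filter(function(cl) cl$label == "occupancy_like", calls)
  vapply(occ, call_center, integer(1), genome_length = len)
}

#' Concordance of occupancy sites between two call sets
#'
#' Occupancy-like summits within `d_max` (modular distance) are matched
#' greedily by increasing distance; the overlap fraction is
#' `matches / union`, a Jaccard-style statistic.
#'
#' @param calls_a,calls_b lists of `peak_call`s (or [screen_dataset()]
#'   results).
#' @param d_max maximum matching distance, bases.
#' @param genome_length circular genome length.
#' @return list with `matches` (data.frame of matched positions) and
#'   `overlap` fraction.
#' @export
site_concordance <- function(calls_a, calls_b, d_max = 100, genome_length) {
  if (!is.null(calls_a$calls)) calls_a <- calls_a$calls
  if (!is.null(calls_b$calls)) calls_b <- calls_b$calls
  ca <- .occupancy_centers(calls_a, genome_length)
  cb <- .occupancy_centers(calls_b, genome_length)
  matches <- data.frame(pos_a = integer(0), pos_b = integer(0),
                        dist = integer(0))
  if (length(ca) && length(cb)) {
    dm <- outer(ca, cb, circ_dist, len = genome_length)
    while (TRUE) {
      best <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = FALSE]
      if (dm[best] > d_max || !is.finite(dm[best])) break
      matches <- rbind(matches,
                       data.frame(pos_a = ca[best[1]], pos_b = cb[best[2]],
                                  dist = dm[best]))
      dm[best[1], ] <- Inf
      dm[, best[2]] <- Inf
      if (all(!is.finite(dm))) break
    }
  }
  union_n <- length(ca) + length(cb) - nrow(matches)
  list(matches = matches,
       overlap = if (union_n > 0) nrow(matches) / union_n else 0)
}

#' Aggregate datasets for one target into an evidence tier
#'
#' Tiers follow the orthogonal-evidence criterion: credible occupancy
#' requires concordant peaks from at least two distinct reagent identities
#' (two different antibodies, or an antibody plus endogenous tagging).
#' Reagent identity is `class + id` and, with `lot_sensitive = TRUE`, also
#' the lot (polyclonal lots can behave as different reagents).
#' `discordant` is flagged whenever some datasets for the target show
#' occupancy-like peaks while others show none; it never raises the tier.
#'
#' @param records list of [dataset_record()]s sharing one target.
#' @param d_max concordance distance, bases.
#' @param corroboration_min threshold for `model_corroborated`.
#' @param lot_sensitive include the lot in reagent identity.
#' @param genome_length circular genome length.
#' @return a list of class `evidence_summary` with `target`, `n_datasets`,
#'   `n_with_peaks`, `orthogonal_reagents_with_peaks`, `tier`
#'   (`orthogonally_replicated`, `replicated_same_reagent`,
#'   `single_dataset`, `discordant_only`, `no_evidence`), `discordant`,
#'   `model_corroborated` and a per-pair `concordance` table.
#' @export
tier_evidence <- function(records, d_max = 100, corroboration_min = 0.5,
                          lot_sensitive = FALSE, genome_length) {
  targets <- unique(vapply(records, `[[`, character(1), "target"))
  if (length(targets) != 1) {
    stop(sprintf("records mix targets: %s", paste(targets, collapse = ", ")))
  }
  ids <- vapply(records, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop("dataset_id values must be unique")
  ## order-independence: canonicalize record order by dataset_id
  records <- records[order(ids)]
  reagent_key <- vapply(records, function(r) {
    paste(r$reagent_class, r$reagent_id,
          if (lot_sensitive) r$lot else "", sep = "|")
  }, character(1))
  has_peaks <- vapply(records, function(r) {
    length(.occupancy_centers(r$calls, genome_length)) > 0
  }, logical(1))
  n <- length(records)
  n_peaks <- sum(has_peaks)
  ## pairwise concordance among peak-bearing datasets
  conc <- data.frame(dataset_a = character(0), dataset_b = character(0),
                     overlap = numeric(0), n_matches = integer(0),
                     orthogonal = logical(0))
  peak_idx <- which(has_peaks)
  if (length(peak_idx) >= 2) {
    for (a in peak_idx) {
      for (b in peak_idx[peak_idx > a]) {
        sc <- site_concordance(records[[a]]$calls, records[[b]]$calls,
                               d_max, genome_length)
        conc <- rbind(conc, data.frame(
          dataset_a = records[[a]]$dataset_id,
          dataset_b = records[[b]]$dataset_id,
          overlap = sc$overlap, n_matches = nrow(sc$matches),
          orthogonal = reagent_key[a] != reagent_key[b]))
      }
    }
  }
  concordant_orth <- any(conc$orthogonal & conc$n_matches > 0)
  concordant_same <- any(!conc$orthogonal & conc$n_matches > 0)
  orth_reagents <- if (concordant_orth) {
    length(unique(reagent_key[peak_idx]))
  } else if (n_peaks > 0) 1L else 0L
  tier <- if (n_peaks == 0) {
    "no_evidence"
  } else if (concordant_orth) {
    "orthogonally_replicated"
  } else if (n_peaks >= 2 && concordant_same) {
    "replicated_same_reagent"
  } else if (n_peaks == 1 && n == 1) {
    "single_dataset"
  } else {
    "discordant_only"
  }
  discordant <- n_peaks > 0 && n_peaks < n
  corr <- vapply(records, function(r) {
    if (is.null(r$corroboration)) NA_real_ else r$corroboration
  }, numeric(1))
  model_corroborated <- any(!is.na(corr[has_peaks]) &
                              corr[has_peaks] >= corroboration_min)
  structure(list(target = targets, n_datasets = n, n_with_peaks = n_peaks,
                 orthogonal_reagents_with_peaks = orth_reagents,
                 tier = tier, discordant = discordant,
                 model_corroborated = model_corroborated,
                 concordance = conc),
            class = "evidence_summary")
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat(sprintf("<evidence_summary> %s: %d/%d dataset(s) with peaks, tier=%s%s%s\n",
              x$target, x$n_with_peaks, x$n_datasets, x$tier,
              if (x$discordant) " [discordant]" else "",
              if (x$model_corroborated) " [model corroborated]" else ""))
  invisible(x)
}

#' Hierarchical clustering of per-dataset signal profiles
#'
#' Tracks are normalized to unit total over unmasked bases and clustered by
#' average linkage on correlation distance (`1 - Pearson r`), the standard
#' display for comparing many datasets' profiles over one small genome.
#' Zero-total tracks are excluded with a warning. Ties in merge heights are
#' resolved by `stats::hclust`'s deterministic ordering of the input rows,
#' so results are reproducible for a given input order.
#'
#' @param track_matrix numeric matrix, one row per dataset (rownames are
#'   dataset labels), columns = genome positions.
#' @param exclude_mask optional logical/0-1 vector marking columns (e.g. the
#'   D-loop) to drop before normalization.
#' @return list with `order` (leaf labels), `merge`, `height`, `hclust`,
#'   `dist` (the full distance matrix).
#' @export
cluster_profiles <- function(track_matrix, exclude_mask = NULL) {
  m <- as.matrix(track_matrix)
  if (nrow(m) < 2) stop("need at least 2 tracks to cluster")
  if (is.null(rownames(m))) rownames(m) <- paste0("dataset", seq_len(nrow(m)))
  if (!is.null(exclude_mask)) {
    m <- m[, !(as.logical(exclude_mask)), drop = FALSE]
  }
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d zero-total track(s): %s", sum(tot == 0),
                    paste(rownames(m)[tot == 0], collapse = ", ")))
    m <- m[tot > 0, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 nonzero tracks remain")
  }
  m <- m / rowSums(m)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[is.na(cc)] <- 0  # constant tracks: define correlation as 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  list(order = rownames(m)[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc, dist = as.matrix(d))
}

#' Summarize many targets into an evidence table
#'
#' @param summaries list of `evidence_summary` objects.
#' @return data.frame, one row per target (a catalog-style table: tier,
#'   counts, discordance and model corroboration flags).
#' @export
evidence_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(target = s$target, n_datasets = s$n_datasets,
               n_with_peaks = s$n_with_peaks,
               orthogonal_reagents = s$orthogonal_reagents_with_peaks,
               tier = s$tier, discordant = s$discordant,
               model_corroborated = s$model_corroborated,
               stringsAsFactors = FALSE)
  }))
}
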