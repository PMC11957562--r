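#' k-mer self-mapping mappability track
#'
#' Emulates the classic self-mapping procedure: the k-mer starting at every
#' position of the contig is realigned against the contig under
#' unique-mapping semantics, and a base is marked fully mappable (1) iff all
#' k k-mers overlapping it realign uniquely. The uniqueness rule mirrors a
#' `-v <mismatches> -k 2 -m 1 --best --strata` aligner contract: among all
#' placements (both orientations, up to `mismatches` mismatches) only the
#' best stratum (minimum mismatch count) is considered, and the k-mer is
#' retained iff exactly one placement exists in that stratum. Since the
#' k-mer always matches its own origin exactly, under `best_strata = TRUE`
#' this reduces to "no second exact occurrence"; setting
#' `best_strata = FALSE` instead discards a k-mer with *any* second
#' placement within the mismatch budget.
#'
#' @param genome a [circular_genome()].
#' @param k k-mer length (default 36, the read length of the libraries the
#'   procedure models).
#' @param mismatches allowed mismatches per placement (default 2).
#' @param circular_kmers if `TRUE`, k-mers are also taken across the origin
#'   (and every base has exactly `k` overlapping k-mers). The default
#'   `FALSE` reproduces a linear reference: no origin-spanning k-mers exist,
#'   so the first and last `k - 1` bases can never be covered by `k` k-mers
#'   and are reported unmappable.
#' @param best_strata see Description.
#' @param count_revcomp whether reverse-complement placements count toward
#'   multiplicity (default `TRUE`, matching double-stranded alignment).
#' @return an object of class `mappability_track` with fields `genome_name`,
#'   `k`, `mismatches`, `values` (0/1 per base).
#' @export
compute_mappability <- function(genome, k = 36, mismatches = 2,
                                circular_kmers = FALSE, best_strata = TRUE,
                                count_revcomp = TRUE) {
  len <- genome$length
  k <- as.integer(k)
  if (len <= 0) stop("empty genome")
  if (k < 1 || k > len) stop("k must lie in [1, genome length]")
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T"))  # N -> NA, mismatches all
  starts <- if (circular_kmers) 0:(len - 1L) else 0:(len - k)
  n <- length(starts)
  ## k-mer matrix, rows = start positions
  idx <- outer(starts, 0:(k - 1L), "+") %% len + 1L
  km <- matrix(code[idx], nrow = n, ncol = k)
  ## one-hot encoding; NA (N base) gets all-zero and mismatches everything
  onehot <- function(m) {
    x <- matrix(0, nrow = nrow(m), ncol = 4L * ncol(m))
    for (b in 1:4) {
      hit <- which(m == b, arr.ind = TRUE)
      if (nrow(hit)) x[cbind(hit[, 1], (hit[, 2] - 1L) * 4L + b)] <- 1
    }
    x
  }
  X <- onehot(km)
  ## reverse-complement k-mers at the same start set (minus-strand loci)
  km_rc <- matrix(5L - km[, k:1, drop = FALSE], nrow = n)
  Xrc <- onehot(km_rc)
  retained <- logical(n)
  chunk <- max(1L, min(n, as.integer(2e7 / n)))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    mm_f <- k - tcrossprod(X[lo:hi, , drop = FALSE], X)
    mm_r <- if (count_revcomp) {
      k - tcrossprod(X[lo:hi, , drop = FALSE], Xrc)
    } else NULL
    for (i in seq_len(hi - lo + 1L)) {
      df <- mm_f[i, ]
      dr <- if (is.null(mm_r)) numeric(0) else mm_r[i, ]
      all_mm <- c(df, dr)
      hits <- all_mm[all_mm <= mismatches + 1e-9]
      retained[lo + i - 1L] <- if (best_strata) {
        best <- min(all_mm)  # always 0: self-placement
        sum(all_mm <= best + 1e-9) == 1L
      } else {
        length(hits) == 1L
      }
    }
  }
  ## per-base count of retained k-mers covering each position
  cover <- integer(len)
  ret_starts <- starts[retained]
  if (length(ret_starts)) {
    d <- integer(len + k)
    tab <- table(ret_starts + 1L)
    d[as.integer(names(tab))] <- as.integer(tab)
    cs <- cumsum(d)
    ## coverage at 1-based pos p = number of retained starts in (p-k, p]
    for (p in seq_len(len)) {
      lo_s <- p - k
      cover[p] <- cs[p] - if (lo_s >= 1L) cs[lo_s] else 0L
    }
    if (circular_kmers) {
      ## starts within k-1 of the end also cover the first bases
      wrap <- ret_starts[ret_starts + k > len]
      for (s in wrap) {
        covered <- (s + k - len)  # number of initial bases covered
        cover[seq_len(covered)] <- cover[seq_len(covered)] + 1L
      }
    }
  }
  values <- as.integer(cover == k)
  structure(list(genome_name = genome$name, k = k, mismatches = mismatches,
                 circular_kmers = circular_kmers, values = values),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat(sprintf("<mappability_track> %s: %d bp, k=%d, %.1f%% mappable\n",
              x$genome_name, length(x$values), x$k, 100 * mean(x$values)))
  invisible(x)
}

#' Write / read a mappability track as bedGraph
#'
#' Adjacent equal values are merged into maximal intervals; the round trip
#' through [read_mappability()] is lossless.
#'
#' @param track a `mappability_track`.
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_mappability <- function(track, path) {
  .write_bedgraph(track$values, track$genome_name, path)
  invisible(path)
}

#' @rdname write_mappability
#' @param genome_name expected contig name.
#' @param k k-mer length to record on the restored track.
#' @export
read_mappability <- function(path, genome_name = NULL, k = NA_integer_) {
  v <- .read_bedgraph(path, genome_name)
  if (!all(v$values %in% c(0, 1))) stop("mappability values must be 0/1")
  structure(list(genome_name = v$genome_name, k = k, mismatches = NA,
                 circular_kmers = NA, values = as.integer(v$values)),
            class = "mappability_track")
}

## Shared bedGraph helpers (run-length merged, 0-based half-open).
.write_bedgraph <- function(values, genome_name, path) {
  r <- rle(as.numeric(values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  gr <- GenomicRanges::GRanges(genome_name,
                               IRanges::IRanges(start = starts + 1L,
                                                end = ends),
                               score = r$values)
  GenomeInfoDb::seqlengths(gr) <- length(values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

.read_bedgraph <- function(path, genome_name = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) stop(sprintf("empty bedGraph: %s", path))
  nm <- as.character(GenomeInfoDb::seqnames(gr)[1])
  if (!is.null(genome_name) && nm != genome_name) {
    stop(sprintf("bedGraph contig '%s' does not match expected '%s'",
                 nm, genome_name))
  }
  len <- max(BiocGenerics::end(gr))
  values <- numeric(len)
  for (i in seq_along(gr)) {
    values[BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <-
      S4Vectors::mcols(gr)$score[i]
  }
  list(genome_name = nm, values = values)
}
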