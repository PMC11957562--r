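## Independent brute-force oracles used to pin down expected values.
## These deliberately share no code with the package implementation.

## Hamming distance between two equal-length character vectors.
.ham <- function(a, b) sum(a != b)

## Brute-force mappability: enumerate every k-mer (character-level), compare
## every pair directly (forward and reverse complement), apply the
## uniqueness rule, then mark a base mappable iff all k covering k-mers are
## retained. O(n^2 k); only for tiny genomes.
oracle_mappability <- function(sequence, k, mismatches, circular,
                               best_strata = TRUE, count_revcomp = TRUE) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  len <- length(chars)
  starts <- if (circular) 0:(len - 1) else 0:(len - k)
  n <- length(starts)
  ## k-mer character matrix, one row per start
  kmat <- matrix(chars[(outer(starts, 0:(k - 1), "+") %% len) + 1],
                 nrow = n)
  rcmat <- matrix(chartr("ACGT", "TGCA", kmat)[, k:1], nrow = n)
  retained <- vapply(seq_len(n), function(i) {
    row <- matrix(kmat[i, ], n, k, byrow = TRUE)
    mm <- rowSums(kmat != row)
    all_mm <- if (count_revcomp) c(mm, rowSums(rcmat != row)) else mm
    if (best_strata) {
      sum(all_mm <= min(all_mm)) == 1
    } else {
      sum(all_mm <= mismatches) == 1
    }
  }, logical(1))
  vapply(0:(len - 1), function(p) {
    covering <- if (circular) {
      which(((p - starts) %% len) < k)
    } else {
      which(starts <= p & p <= starts + k - 1)
    }
    as.integer(length(covering) == k && all(retained[covering]))
  }, integer(1))
}

## Census of exact k-mer multiplicities (for the "no repeated 36-mer on a
## random 1 kb sequence" check), again character-level and circular.
oracle_kmer_census <- function(sequence, k) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  len <- length(chars)
  km <- vapply(0:(len - 1), function(s) {
    paste(chars[((s + 0:(k - 1)) %% len) + 1], collapse = "")
  }, character(1))
  table(km)
}

## Independent vector rotation (position r becomes position 0).
rotate_vec_test <- function(x, r) {
  n <- length(x)
  r <- ((r %% n) + n) %% n
  if (r == 0) x else c(x[(r + 1):n], x[1:r])
}

## A deterministic small genome + reads world reused across tests.
make_test_world <- function(seed = 1, length = 6000L, n_reads = 20000L,
                            site_pos = c(1500L, 4000L),
                            artifact_pos = 300L) {
  g <- generate_circular_genome(length, 0.44, seed = seed)
  sites <- truth_sites(c(site_pos, artifact_pos),
                       c(rep("+", length(site_pos)), "both"),
                       NA, 20,
                       c(rep("occupancy", length(site_pos)), "artifact"))
  cfg <- sim_config(n_reads, background_fraction = 0.5, seed = seed + 100L)
  list(genome = g, sites = sites,
       aset = simulate_reads(g, sites, cfg), config = cfg)
}
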