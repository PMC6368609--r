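# Independent oracles used across test files. Each is a straight-line
# restatement of the definition, kept free of package internals.

# mHG statistic of one membership ordering (direct formula)
oracle_mhg_stat <- function(membership) {
  N <- length(membership)
  K <- sum(membership)
  k <- cumsum(membership)
  min(phyper(k - 1, K, N - K, seq_len(N), lower.tail = FALSE))
}

# exact mHG p-value by exhaustive enumeration of all C(N, K) placements
oracle_mhg_p <- function(membership) {
  N <- length(membership)
  K <- sum(membership)
  if (K == 0L) return(1)
  s_obs <- oracle_mhg_stat(membership)
  combs <- utils::combn(N, K)
  stats <- apply(combs, 2L, function(idx) {
    mem <- rep(FALSE, N); mem[idx] <- TRUE
    oracle_mhg_stat(mem)
  })
  mean(stats <= s_obs * (1 + 1e-12))
}

# brute-force droplet verdict: literal restatement of the mRNA rules and
# the three antibody exclusion criteria
oracle_droplet <- function(n_genes, mito_fraction, type_counts,
                           donor_counts) {
  mrna_ok <- !(n_genes <= 500 || mito_fraction >= 0.20)
  set_verdict <- function(cnt) {
    srt <- sort(cnt, decreasing = TRUE)
    total <- sum(cnt)
    top <- srt[1L]
    second <- if (length(srt) >= 2L) srt[2L] else 0
    fail1 <- total < 10
    fail2 <- second > 0.10 * top
    fail3 <- top < 0.75 * total
    !(fail1 || fail2 || fail3)
  }
  t_ok <- set_verdict(type_counts)
  d_ok <- set_verdict(donor_counts)
  retained <- mrna_ok && t_ok && d_ok
  list(retained = retained,
       cell_type = if (retained) names(type_counts)[which.max(type_counts)]
                   else NA_character_,
       donor = if (retained) names(donor_counts)[which.max(donor_counts)]
               else NA_character_)
}

# per-base peak-to-gene oracle: a gene is a target when any base of any
# peak lies in the rule's window (0-based half-open coordinates)
oracle_peak_target <- function(peaks, gene, rule) {
  tss <- if (gene$strand == "+") gene$start else gene$end - 1
  in_window <- function(p) {
    if (rule == "body2kb") {
      p >= gene$start - 2000 && p < gene$end + 2000
    } else {
      d <- if (gene$strand == "+") p - tss else tss - p
      d >= -2000 && d < 1000
    }
  }
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != gene$chrom) next
    for (p in seq(peaks$start[i], peaks$end[i] - 1))
      if (in_window(p)) return(TRUE)
  }
  FALSE
}

# small bulk matrix for IO / preprocessing tests
tiny_bulk <- function(seed = 1L) {
  simulate_bulk(bulk_sim_design(n_donors = 2L, n_genes = 50L,
                                n_replicates = 1L, seed = seed))
}
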