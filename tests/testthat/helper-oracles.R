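# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# Quadratic scanner: test every (start, n) pair directly against the four
# cysteine positions. Coordinates 0-based.
brute_force_zf_scan <- function(sequence, spacings = c(17L, 18L, 19L, 20L)) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- list()
  for (s in 0:(L - 1)) {
    for (n in spacings) {
      last <- s + n + 7L                     # 0-based fourth-Cys offset
      if (last >= L) next
      if (chars[s + 1L] == "C" && chars[s + 4L] == "C" &&
          chars[s + n + 5L] == "C" && chars[last + 1L] == "C") {
        out[[length(out) + 1L]] <- data.frame(start = s, spacing_n = n)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), spacing_n = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$spacing_n), , drop = FALSE]
}

# Random protein sequence over the 20-letter alphabet.
random_protein <- function(len, cys_weight = 1) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  w <- rep(1, 20); w[2] <- cys_weight
  paste(sample(aa, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}

# Exhaustive global alignment score by enumerating all alignments of two
# short strings (recursion over edit operations with affine gaps: a gap run
# of length L costs gap_open + L * gap_extend).
enumerate_align_score <- function(a, b, match = 1, mismatch = -1,
                                  gap_open = -2, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: (i consumed of a, j consumed of b, last op: 0 none/diag, 1 gap in
  # b (a aligned to -), 2 gap in a)
  rec <- function(i, j, last, score) {
    if (i == length(ca) && j == length(cb)) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i < length(ca) && j < length(cb)) {
      s <- if (ca[i + 1] == cb[j + 1]) match else mismatch
      rec(i + 1, j + 1, 0L, score + s)
    }
    if (i < length(ca)) {
      open <- if (last == 1L) 0 else gap_open
      rec(i + 1, j, 1L, score + open + gap_extend)
    }
    if (j < length(cb)) {
      open <- if (last == 2L) 0 else gap_open
      rec(i, j + 1, 2L, score + open + gap_extend)
    }
  }
  rec(0L, 0L, 0L, 0)
  best
}

# Positionwise brute-force motif scan of a DNA string on both strands,
# returning 0-based starts. IUPAC handled by explicit class tables.
IUPAC_CLASSES <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

brute_force_motif_scan <- function(dna, motif) {
  bases <- strsplit(dna, "")[[1]]
  pat <- strsplit(motif, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- rev(unname(comp[strsplit(motif, "")[[1]]]))
  # for the reverse complement of an IUPAC pattern, complement the classes
  rc_classes <- rev(lapply(pat, function(l) unname(comp[IUPAC_CLASSES[[l]]])))
  fwd_classes <- lapply(pat, function(l) IUPAC_CLASSES[[l]])
  L <- length(bases); m <- length(pat)
  hit <- function(classes, s) {
    all(vapply(seq_len(m), function(k) bases[s + k] %in% classes[[k]],
               logical(1)))
  }
  out <- list()
  if (L >= m) {
    for (s in 0:(L - m)) {
      if (hit(fwd_classes, s)) {
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "+")
      }
      if (hit(rc_classes, s)) {
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "-")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character()))
  }
  do.call(rbind, out)
}

# Exact two-sided rank-sum p-value by enumeration over all label
# assignments (choose(n_total, n_x) splits), matching the two-sided rule
# 2 * min(P(U <= u), P(U >= u)) capped at 1.
enumerate_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(vals), nx)
  u_obs <- sum(rank(vals)[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(idx, 2, function(ii) {
    sum(rank(vals)[ii]) - nx * (nx + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exhaustive hypergeometric upper tail P(X >= k) by enumerating all
# C(N, n) draws is infeasible in general; for N <= 20 use the closed
# combinatorial sum, which is itself an independent path from phyper.
enumerate_hyper_p <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
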