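# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA_LETTERS) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- CCCH scan oracle: enumerate every (c1, c2, c3, h) quadruple within the
# spacing bounds, then replay the leftmost / greedy / non-overlap rules on
# the candidate list.
ccch_oracle <- function(seq, d1 = c(4L, 15L), d2 = c(4L, 7L), d3 = c(3L, 4L),
                        greedy = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  cs <- which(ch == "C")
  hs <- which(ch == "H")
  cand <- list()
  for (c1 in cs) for (c2 in cs) {
    s1 <- c2 - c1 - 1L
    if (s1 < d1[1] || s1 > d1[2]) next
    for (c3 in cs) {
      s2 <- c3 - c2 - 1L
      if (s2 < d2[1] || s2 > d2[2]) next
      for (h in hs) {
        s3 <- h - c3 - 1L
        if (s3 < d3[1] || s3 > d3[2]) next
        cand[[length(cand) + 1L]] <- c(c1, c2, c3, h, s1, s2, s3)
      }
    }
  }
  taken <- list()
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cursor <- 1L
    repeat {
      live <- cand[cand[, 1] >= cursor, , drop = FALSE]
      if (nrow(live) == 0) break
      lead <- min(live[, 1])
      at <- live[live[, 1] == lead, , drop = FALSE]
      # lexicographic order on (d1, d2, d3)
      ord <- order(at[, 5], at[, 6], at[, 7],
                   decreasing = greedy, method = "radix")
      pick <- at[ord[1], ]
      taken[[length(taken) + 1L]] <- pick
      cursor <- pick[4] + 1L
    }
  }
  if (length(taken) == 0)
    return(data.frame(start = integer(0), end = integer(0), d1 = integer(0),
                      d2 = integer(0), d3 = integer(0)))
  m <- do.call(rbind, taken)
  data.frame(start = m[, 1], end = m[, 4], d1 = m[, 5], d2 = m[, 6],
             d3 = m[, 7])
}

# --- NES oracle: slide a cursor; at every position test 11/10/10/9-residue
# windows against the consensus character classes in the backtracking
# preference order (3,3), (3,2), (2,3), (2,2); jump past each accepted hit.
nes_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  in_lv <- ch %in% c("L", "V")
  in_livfm <- ch %in% c("L", "I", "V", "F", "M")
  in_last <- ch %in% c("L", "I", "M", "T", "K", "D")
  is_l <- ch == "L"
  combos <- list(c(3L, 3L), c(3L, 2L), c(2L, 3L), c(2L, 2L))
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n - 8L) {
    hit_len <- NA_integer_
    if (in_lv[i]) {
      for (g in combos) {
        a2 <- i + 1L + g[1]
        a3 <- a2 + 1L + g[2]
        a4 <- a3 + 2L
        if (a4 <= n && in_livfm[a2] && is_l[a3] && in_last[a4]) {
          hit_len <- a4 - i + 1L
          break
        }
      }
    }
    if (!is.na(hit_len)) {
      starts <- c(starts, i); ends <- c(ends, i + hit_len - 1L)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

# --- Gotoh affine-gap global alignment score (match 1, mismatch 0).
gotoh_score <- function(a, b, match = 1, mismatch = 0, gap_open = 10,
                        gap_ext = 0.5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in y (deletion)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in x (insertion)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- average residue masses recomputed from elemental composition and
# standard atomic weights (independent of the package's mass table)
residue_mass_from_atoms <- function() {
  w <- c(C = 12.011, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065)
  comp <- list(  # residue (= amino acid minus water) atom counts
    A = c(3, 5, 1, 1, 0), R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0), C = c(3, 5, 1, 1, 1), E = c(5, 7, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0), G = c(2, 3, 1, 1, 0), H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1), F = c(9, 9, 1, 1, 0), P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0), T = c(4, 7, 1, 2, 0), W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0), V = c(5, 9, 1, 1, 0))
  vapply(comp, function(k) sum(k * w[c("C", "H", "N", "O", "S")]), numeric(1))
}

mw_oracle <- function(seq) {
  tab <- residue_mass_from_atoms()
  sum(tab[strsplit(seq, "")[[1]]]) + 2 * 1.00794 + 15.9994
}

# --- grid-search pI oracle
pi_grid_oracle <- function(seq, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- ccchfamily::netCharge(seq, grid)
  grid[which.min(abs(q))]
}

# motif/hit interval keys for truth comparison
interval_key <- function(df) paste(df$protein_id, df$start, df$end)

# numeric matrix view of a hit table for oracle comparison
num_mat <- function(df) {
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  unname(m)
}
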