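# Independent brute-force oracles, deliberately written with different
# machinery than the package (regex-free character loops, table()), plus
# small random-sequence helpers shared across test files.

random_seq <- function(L, symbols) {
  paste(sample(symbols, L, replace = TRUE), collapse = "")
}

# overlapping occurrences of word `m` in `s` by explicit position scan
naive_count <- function(s, m) {
  L <- nchar(s)
  w <- nchar(m)
  if (L < w) return(0L)
  hits <- 0L
  for (p in seq_len(L - w + 1L)) {
    if (substr(s, p, p + w - 1L) == m) hits <- hits + 1L
  }
  hits
}

# CTD oracles over a 3-group partition, position-by-position
naive_group_of <- function(ch, partition) {
  for (j in 1:3) if (ch %in% partition[[j]]) return(j)
  NA_integer_
}

naive_groups <- function(s, partition) {
  unname(vapply(strsplit(s, "")[[1]], naive_group_of, 0L, partition))
}

naive_ctd_c <- function(s, partition) {
  g <- naive_groups(s, partition)
  vapply(1:3, function(j) sum(g == j), 0L) / nchar(s)
}

naive_ctd_t <- function(s, partition) {
  g <- naive_groups(s, partition)
  out <- c(0L, 0L, 0L)
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (i in seq_len(length(g) - 1L)) {
    for (r in 1:3) {
      if ((g[i] == pairs[r, 1] && g[i + 1] == pairs[r, 2]) ||
          (g[i] == pairs[r, 2] && g[i + 1] == pairs[r, 1])) {
        out[r] <- out[r] + 1L
      }
    }
  }
  out / (length(g) - 1L)
}

naive_ctd_d <- function(s, partition) {
  g <- naive_groups(s, partition)
  L <- length(g)
  out <- numeric(0)
  for (j in 1:3) {
    pos <- which(g == j)
    if (length(pos) == 0L) {
      out <- c(out, rep(0, 5))
    } else {
      n <- length(pos)
      anchors <- c(pos[1],
                   vapply(c(0.25, 0.5, 0.75, 1), function(q) {
                     pos[max(1L, as.integer(ceiling(q * n)))]
                   }, 0))
      out <- c(out, anchors / L)
    }
  }
  out
}

# metrics recomputed straight from the raw label vectors
naive_metrics <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
  fp <- sum(y == 0 & yhat == 1); tn <- sum(y == 0 & yhat == 0)
  den2 <- (tp + fn) * (tn + fn) * (tp + fp) * (tn + fp)
  list(sn = tp / (tp + fn), sp = tn / (tn + fp),
       acc = (tp + tn) / length(y),
       mcc = if (den2 > 0) (tp * tn - fp * fn) / sqrt(den2) else 0)
}

protein_symbols <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
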