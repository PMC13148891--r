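# Independent brute-force oracles. These re-derive expected results with
# naive per-window loops and textbook formulas, deliberately sharing no code
# with the package implementation.

# All-windows scan over a set of frame translations: walks every window
# start explicitly and counts mismatching positions one window at a time.
# comparator: "hamming" compares residues; "property" compares class labels
# (residues without a class, i.e. X, always mismatch). Windows containing a
# stop are skipped. Returns the same columns and ordering as the scanners.
brute_scan <- function(frames, query, comparator = "hamming",
                       max_distance = nchar(query), alphabet = NULL) {
  k <- nchar(query)
  q <- strsplit(query, "")[[1]]
  if (comparator == "property") q <- unname(alphabet[q])
  rows <- list()
  for (fr in frames) {
    chars <- strsplit(fr$peptide, "")[[1]]
    if (length(chars) < k) next
    for (s in seq_len(length(chars) - k + 1)) {
      w <- chars[s:(s + k - 1)]
      if (any(w == "*")) next
      if (comparator == "property") {
        wc <- unname(alphabet[w])
        d <- sum(is.na(wc) | wc != q)
      } else {
        d <- sum(w != q)
      }
      if (d <= max_distance) {
        rows[[length(rows) + 1]] <- data.frame(
          source = fr$source, frame = fr$frame, pep_offset = s - 1L,
          nt_start = fr$nt_start[s],
          window = paste(chars[s:(s + k - 1)], collapse = ""),
          distance = as.integer(d), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(source = character(0), frame = integer(0),
                      pep_offset = integer(0), nt_start = integer(0),
                      window = character(0), distance = integer(0)))
  out <- do.call(rbind, rows)
  forder <- match(out$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  out <- out[order(out$distance, out$source, forder, out$pep_offset), ]
  rownames(out) <- NULL
  out
}

# strip the mode column so scanner output can be compared to the oracle
hit_core <- function(hits) {
  out <- hits[, c("source", "frame", "pep_offset", "nt_start", "window",
                  "distance")]
  rownames(out) <- NULL
  out
}

# textbook R^2: 1 - SS_res / SS_tot for a simple linear regression computed
# from closed-form slope/intercept
brute_r_squared <- function(x, y) {
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - bx * mean(x)
  1 - sum((y - (a + bx * x))^2) / sum((y - mean(y))^2)
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# logistic time course value
logistic_val <- function(t, L, k, t50) L / (1 + exp(-k * (t - t50)))
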