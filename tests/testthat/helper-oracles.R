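# Independent oracles, written against the procedure definitions directly
# (no shared code with the package implementations they check).

# Literal interpreter of the run-length correction procedure: scan the raw
# sequence for maximal constant segments, flip the leftmost interior segment
# of length exactly i whose flanking segment lengths satisfy the rule, with
# immediate effect; i = 1..k in order; repeat the whole k-sweep to a fixed
# point.
literal_correction <- function(seq, k = 6) {
  seg_bounds <- function(s) {
    starts <- c(1, which(diff(s) != 0) + 1)
    ends <- c(starts[-1] - 1, length(s))
    cbind(starts, ends)
  }
  repeat {
    before <- seq
    for (i in seq_len(k)) {
      repeat {
        b <- seg_bounds(seq)
        ns <- nrow(b)
        done <- TRUE
        if (ns >= 3) {
          for (j in 2:(ns - 1)) {
            num <- b[j, 2] - b[j, 1] + 1
            if (num != i) next
            jl <- b[j - 1, 2] - b[j - 1, 1] + 1
            jr <- b[j + 1, 2] - b[j + 1, 1] + 1
            if ((jl >= i && jr >= i + 1) || (jr >= i && jl >= i + 1)) {
              seq[b[j, 1]:b[j, 2]] <- seq[b[j - 1, 2]]
              done <- FALSE
              break
            }
          }
        }
        if (done) break
      }
    }
    if (identical(seq, before)) return(seq)
  }
}

# Mann-Whitney pair statistic: fraction of (positive, negative) pairs where
# the positive outscores the negative, ties counted one half.
auc_pair_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (p in sp) total <- total + sum(p > sn) + 0.5 * sum(p == sn)
  total / (length(sp) * length(sn))
}

# All binary sequences of a given length.
all_binary_seqs <- function(len) {
  m <- as.matrix(expand.grid(rep(list(0:1), len)))
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}
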