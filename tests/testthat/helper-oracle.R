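# Independent brute-force oracle for aggregated isotope distributions:
# convolve the single-atom distribution of every atom one at a time,
# aggregating by nucleon offset, with no pruning. Deliberately naive and
# kept free of the package's convolution code.

oracle_isotope_distribution <- function(counts) {
  iso_tab <- list(
    C = list(off = c(0, 1), mass = c(12.000000, 13.003355),
             ab = c(0.989300, 0.010700)),
    H = list(off = c(0, 1), mass = c(1.007825, 2.014102),
             ab = c(0.999885, 0.000115)),
    N = list(off = c(0, 1), mass = c(14.003074, 15.000109),
             ab = c(0.996360, 0.003640)),
    O = list(off = c(0, 1, 2), mass = c(15.994915, 16.999132, 17.999160),
             ab = c(0.997570, 0.000380, 0.002050)),
    S = list(off = c(0, 1, 2, 4),
             mass = c(31.972071, 32.971459, 33.967867, 35.967081),
             ab = c(0.949900, 0.007500, 0.042500, 0.000100)))
  dist <- data.frame(offset = 0L, ab = 1, am = 0)
  for (e in names(counts)) {
    if (is.na(counts[e]) || counts[e] == 0) next
    atom <- iso_tab[[e]]
    for (k in seq_len(counts[e])) {
      new <- list()
      for (i in seq_len(nrow(dist))) {
        for (j in seq_along(atom$off)) {
          new[[length(new) + 1L]] <- data.frame(
            offset = dist$offset[i] + atom$off[j],
            ab = dist$ab[i] * atom$ab[j],
            am = dist$ab[i] * atom$ab[j] * atom$mass[j] +
              dist$am[i] * atom$ab[j])
        }
      }
      new <- do.call(rbind, new)
      dist <- do.call(rbind, lapply(split(new, new$offset), function(g)
        data.frame(offset = g$offset[1], ab = sum(g$ab), am = sum(g$am))))
      dist <- dist[order(dist$offset), , drop = FALSE]
      dist <- dist[dist$ab > 0, , drop = FALSE]
    }
  }
  data.frame(offset = dist$offset, mass = dist$am / dist$ab,
             abundance = dist$ab)
}

# 20-residue test sequence containing every standard amino acid once;
# lysine sits at position 12
test_sequence <- function() "GASPVTLINDQKEMHFRYWC"
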