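# shared fixtures built in code

# binary adjacency rows with prescribed support sizes and overlap, padded
# to a common length
binary_pair_matrix <- function(deg_x, deg_y, overlap, len = 12) {
  stopifnot(overlap <= min(deg_x, deg_y), deg_x + deg_y - overlap <= len)
  x <- numeric(len); y <- numeric(len)
  x[seq_len(deg_x)] <- 1
  y_start <- deg_x - overlap
  y[y_start + seq_len(deg_y)] <- 1
  M <- rbind(X = x, Y = y)
  colnames(M) <- paste0("k", seq_len(len))
  M
}

# small deterministic recording
toy_recording <- function(n_chan = 2, n = 2000, fs = 200, seed = 1) {
  set.seed(seed)
  seeg_recording(matrix(rnorm(n_chan * n), n_chan),
                 paste0("A", seq_len(n_chan)), fs)
}

# one h2 value between two freshly generated independent channels
null_h2 <- function(duration_s = 5.12, fs = 200) {
  rec <- generate_coupled_signals(coupling_spec(),
                                  channel_labels = c("A", "B"),
                                  duration_s = duration_s, fs = fs)
  h2(rec$samples[1, ], rec$samples[2, ])
}
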