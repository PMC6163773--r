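toy_feature_corpus <- function(seed = 1, n = c(a = 9, b = 9, c = 5)) {
  set.seed(seed)
  mus <- list(a = c(0, 0), b = c(4, 0), c = c(2, 3))
  out <- list()
  k <- 0
  for (cl in names(n)) {
    for (j in seq_len(n[[cl]])) {
      k <- k + 1
      out[[k]] <- feature_seq(
        matrix(stats::rnorm(40 * 2, mean = rep(mus[[cl]], each = 40)), 40, 2),
        "toy", clip_id = sprintf("%s_%02d", cl, j), label = cl)
    }
  }
  out
}
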