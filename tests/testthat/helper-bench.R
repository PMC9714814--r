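# Build a CCIMatrix and DistanceRanges directly so the classifier input is
# fully controlled.
benchToy <- function(nPerClass, scoreByClass, jitter = 0.02, seed = 1) {
  set.seed(seed)
  n <- 3 * nPerClass
  # enough cell types for n unordered pairs
  Tn <- ceiling((1 + sqrt(1 + 8 * n)) / 2)
  types <- sprintf("ct%03d", seq_len(Tn))
  cmb <- utils::combn(types, 2)[, seq_len(n), drop = FALSE]
  lab <- rep(c("short", "mid", "long"), each = nPerClass)
  score <- scoreByClass[lab] + runif(n, -jitter, jitter)
  m <- matrix(0, Tn, Tn, dimnames = list(types, types))
  for (i in seq_len(n)) {
    m[cmb[1, i], cmb[2, i]] <- score[i]
    m[cmb[2, i], cmb[1, i]] <- score[i]
  }
  cci <- new("CCIMatrix", scores = m, method = "bray_curtis",
             metadata = list())
  ranges <- new("DistanceRanges",
    pairs = data.frame(
      typeA = cmb[1, ], typeB = cmb[2, ],
      distance = seq_len(n),
      range = factor(lab, levels = c("short", "mid", "long"))
    ),
    mixture = list(means = c(1, 2, 3), variances = c(1, 1, 1),
                   weights = c(1, 1, 1) / 3)
  )
  list(cci = cci, ranges = ranges)
}
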