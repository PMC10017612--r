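# Shared fixtures: tiny hand-built trial tables and independent oracles.

paradigms <- list(
  univalent = make_paradigm("univalent"),
  bivalent_congruency = make_paradigm("bivalent_congruency"),
  three_key = make_paradigm("three_key"))

# Independent triplet counter: brute-force enumeration of all index triples
# (i-2, i-1, i), kept deliberately naive.
brute_triplets <- function(task) {
  aba <- 0L; cba <- 0L
  for (i in seq_along(task)) {
    if (i < 3L) next
    if (task[i] == task[i - 2L]) aba <- aba + 1L else cba <- cba + 1L
  }
  c(aba = aba, cba = cba)
}

# Exhaustive grid-search MLE oracle on a (resolution x resolution) grid of
# (T, R); returns the argmax. Vectorized but independent of fit_mpt().
grid_mle <- function(counts, model_id, resolution = 1001L) {
  g <- seq(0, 1, length.out = resolution)
  TT <- rep(g, times = resolution)
  RR <- rep(g, each = resolution)
  p <- category_probabilities(model_id, TT, RR)
  ll <- rep(0, length(TT))
  for (j in seq_along(p)) {
    cj <- counts[[names(p)[j]]]
    if (cj > 0) ll <- ll + cj * log(pmax(p[[j]], 1e-300))
  }
  i <- which.max(ll)
  c(T = TT[i], R = RR[i])
}

# Minimal hand-built trial table: one participant, one block, RTs and
# accuracy chosen per test.
toy_trials <- function(correct, rt_ms, timeout = rep(FALSE, length(correct)),
                       task = rep(c("a", "b", "c"), length.out = length(correct)),
                       block = 1L, participant = 1L) {
  data.frame(participant = participant, block = block,
             trial = seq_along(correct), task = task,
             stim_id = paste0("s", seq_along(correct)),
             rt_ms = rt_ms, timeout = timeout, correct = correct,
             stringsAsFactors = FALSE)
}

# Small simulated dataset used by several seqcost tests
simulate_small <- function(latent, n_participants = 10, n_blocks = 2,
                           block_length = 60, seed = 42,
                           paradigm = paradigms$three_key) {
  simulate_experiment(paradigm, n_participants, n_blocks, block_length,
                      latent, seed = seed)
}
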