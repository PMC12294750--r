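# Shared fixtures, built in code.

# four-token hand corpus: A->w1, A->w1, A->w2, B->w1
hand_corpus <- function() {
  token_table(word = c("w1", "w1", "w2", "w1"),
              context = c("A", "A", "A", "B"))
}

# a random token table with durations, for round-trip and property tests
random_tokens <- function(n, n_words = 12, n_contexts = 8, seed = 1) {
  set.seed(seed)
  token_table(word = sample(paste0("w", seq_len(n_words)), n, replace = TRUE),
              context = sample(paste0("c", seq_len(n_contexts)), n,
                               replace = TRUE),
              duration_log = round(rnorm(n, -2, 0.5), 6))
}

# brute-force informativity straight from the definition: loop over the
# word's tokens, average -log of the relative frequency counted by hand
brute_force_informativity <- function(tokens, word) {
  rows <- which(tokens$word == word)
  surprisals <- vapply(rows, function(i) {
    cx <- tokens$context[i]
    in_cx <- tokens$context == cx
    p <- sum(tokens$word[in_cx] == word) / sum(in_cx)
    -log(p)
  }, numeric(1))
  mean(surprisals)
}
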