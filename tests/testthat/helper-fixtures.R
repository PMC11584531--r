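# Shared test fixtures and independent oracles.

# Build a post_collection directly from title/body vectors.
make_posts <- function(title, body = rep("", length(title)),
                       timestamp = seq_along(title),
                       post_id = sprintf("p%03d", seq_along(title))) {
  out <- data.frame(post_id = post_id, timestamp = as.numeric(timestamp),
                    title = title, body = body, stringsAsFactors = FALSE)
  out$text <- normalize_post_text(title, body)
  class(out) <- c("post_collection", "data.frame")
  out
}

tiny_lexicon <- function() {
  drug_lexicon(
    entries = list(
      topiramate = c("topiramate", "topamax"),
      propranolol = c("propranolol", "inderal"),
      erenumab = c("erenumab", "aimovig")
    ),
    cgrp_class = "erenumab"
  )
}

# Independent token-mode Welch oracle: materializes the 0/1 indicator
# vector over every token position and evaluates the Welch formula on the
# numeric vectors (population variance of the indicators).
oracle_welch_token <- function(count1, n1, count2, n2) {
  v1 <- c(rep(1, count1), rep(0, n1 - count1))
  v2 <- c(rep(1, count2), rep(0, n2 - count2))
  m1 <- mean(v1); m2 <- mean(v2)
  s1 <- mean((v1 - m1)^2)
  s2 <- mean((v2 - m2)^2)
  se2 <- s1 / n1 + s2 / n2
  if (se2 == 0) {
    if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    (m1 - m2) / sqrt(se2)
  }
}

# Tiny random corpus of <= max_texts texts and <= max_tokens tokens drawn
# from a small vocabulary.
random_tiny_corpus <- function(label, max_texts = 5L, max_tokens = 20L,
                               vocab = c("aaa", "bbb", "ccc", "ddd")) {
  n_texts <- sample.int(max_texts, 1L)
  toks <- lapply(seq_len(n_texts), function(i) {
    sample(vocab, sample.int(max(1L, max_tokens %/% n_texts), 1L),
           replace = TRUE)
  })
  build_corpus(label, sprintf("%s%03d", label, seq_len(n_texts)), toks)
}

paper_study_drugs <- c("propranolol", "topiramate", "erenumab", "fremanezumab")

# One seeded study-scale run of a drug-vs-control-group comparison on
# synthetic data, returning the comparison result.
synthetic_drug_vs_group <- function(seed, drug = "topiramate",
                                    group = "group2",
                                    planted_signals = list(),
                                    test_config = pharmakeyword::test_config()) {
  cfg <- synth_config_paper_like(seed = seed, planted_signals = planted_signals)
  posts <- generate_posts(cfg)
  plan <- study_plan(
    comparisons = list(list(label = paste0(drug, "_vs_", group),
                            s = drug, t = group)),
    seed = seed, test_config = test_config, study_drugs = paper_study_drugs)
  run_study(posts, plan = plan)$results[[1L]]
}
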