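test_that("synth_config validates its parameters", {
  expect_error(synth_config(100, drug_prevalence = c(aspirin = 0.1)),
               "not in lexicon")
  expect_error(synth_config(100, drug_prevalence = c(topiramate = 1.5)))
  expect_error(synth_config(
    100, drug_prevalence = c(topiramate = 0.1),
    planted_signals = list(list(drug = "erenumab", word = "abc",
                                rate_ratio = 2))),
    "without a prevalence")
  expect_error(synth_config(
    100, drug_prevalence = c(topiramate = 0.1),
    planted_signals = list(list(drug = "topiramate", word = "x1",
                                rate_ratio = 2))),
    "3 letters")
  cfg <- synth_config_paper_like(seed = 2)
  expect_equal(cfg$n_posts, 22467L)
  expect_equal(unname(cfg$drug_prevalence["fremanezumab"]), 0.0032)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_posts = 400, vocab_size = 300,
                      drug_prevalence = c(topiramate = 0.1),
                      planted_signals = list(list(drug = "topiramate",
                                                  word = "appetite",
                                                  rate_ratio = 4)),
                      seed = 77)
  p1 <- generate_posts(cfg)
  p2 <- generate_posts(cfg)
  expect_identical(p1$text, p2$text)
  expect_identical(p1$timestamp, p2$timestamp)
  p3 <- generate_posts(synth_config(n_posts = 400, vocab_size = 300,
                                    drug_prevalence = c(topiramate = 0.1),
                                    seed = 78))
  expect_false(identical(p1$text, p3$text))
  # generation leaves the session RNG untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_posts(cfg))
  expect_identical(.Random.seed, before)
})

test_that("zero prevalence yields an all-control pool", {
  cfg <- synth_config(n_posts = 300, vocab_size = 200,
                      drug_prevalence = c(topiramate = 0, propranolol = 0),
                      seed = 3)
  posts <- generate_posts(cfg)
  asg <- build_corpora(posts, default_lexicon(),
                       c("topiramate", "propranolol"))
  expect_length(asg$drug_corpora$topiramate, 0L)
  expect_equal(sort(asg$control_pool), sort(posts$post_id))
})

test_that("empirical word frequencies track the Zipf target", {
  cfg <- synth_config(n_posts = 10000, seed = 123)
  posts <- generate_posts(cfg)
  toks <- unlist(tokenize(posts$text))
  counts <- table(toks)
  total <- length(toks)
  ranks <- 1:20
  target <- ranks^(-cfg$zipf_exponent) /
    sum(seq_len(cfg$vocab_size)^(-cfg$zipf_exponent))
  vocab20 <- names(sort(counts, decreasing = TRUE))[ranks]
  emp <- as.numeric(counts[vocab20]) / total
  expect_true(all(abs(emp - target) / target < 0.05))
})

test_that("realized drug-mention prevalence matches the configuration", {
  cfg <- synth_config(n_posts = 10000,
                      drug_prevalence = c(topiramate = 0.0633,
                                          fremanezumab = 0.0032),
                      seed = 456)
  posts <- generate_posts(cfg)
  lex <- default_lexicon()
  for (d in names(cfg$drug_prevalence)) {
    hits <- sum(mentions_drug(posts$text, lex$entries[[d]]))
    p <- cfg$drug_prevalence[[d]]
    ci <- qbinom(c(0.005, 0.995), cfg$n_posts, p)
    expect_gte(hits, ci[1])
    expect_lte(hits, ci[2])
  }
})

test_that("planted signals raise the word's frequency in the drug corpus", {
  cfg <- synth_config(n_posts = 6000, vocab_size = 1000,
                      drug_prevalence = c(topiramate = 0.2),
                      planted_signals = list(list(drug = "topiramate",
                                                  word = "appetite",
                                                  rate_ratio = 8,
                                                  base_rank = 50)),
                      seed = 9)
  posts <- generate_posts(cfg)
  hit <- mentions_drug(posts$text, default_lexicon()$entries$topiramate)
  rate_in <- function(texts) {
    tok <- unlist(tokenize(texts))
    mean(tok == "appetite")
  }
  expect_gt(rate_in(posts$text[hit]), 4 * rate_in(posts$text[!hit]))
})

test_that("burstiness draws clump words within texts", {
  base <- synth_config(n_posts = 250, vocab_size = 150,
                       post_length_mean = 40, seed = 55)
  bursty <- synth_config(n_posts = 250, vocab_size = 150,
                         post_length_mean = 40, burstiness = 0.5, seed = 55)
  disp <- function(cfg) {
    posts <- generate_posts(cfg)
    corp <- corpus_from_posts(posts, posts$post_id, "x")
    # mean within-text repetition of the most common word
    w <- which.max(corp$vocab_counts)
    cells <- corp$cells[corp$cells$word_idx == w, ]
    mean(cells$count)
  }
  expect_gt(disp(bursty), disp(base))
  expect_identical(generate_posts(bursty)$text, generate_posts(bursty)$text)
})

test_that("score_recovery computes precision, recall and false flags", {
  fake <- function(retained, tested) {
    structure(list(keywords = retained,
                   table = data.frame(word = tested,
                                      stringsAsFactors = FALSE)),
              class = "corpus_comparison")
  }
  m <- score_recovery(fake(c("appetite", "taste"),
                           c("appetite", "taste", "posts")), "appetite")
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 0.5)
  expect_equal(m$false_flag_rate, 1 / 2)
  m2 <- score_recovery(fake(character(), c("appetite", "posts")), "appetite")
  expect_equal(m2$recall, 0)
  expect_true(is.na(m2$precision))
  m3 <- score_recovery(fake(c("appetite"), c("appetite", "posts")), "appetite")
  expect_equal(m3$precision, 1)
  expect_equal(m3$recall, 1)
  m4 <- score_recovery(fake(character(), c("posts")), character())
  expect_equal(m4$precision, 1)
  expect_equal(m4$recall, 1)
})
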