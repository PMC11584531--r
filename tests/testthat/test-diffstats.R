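test_that("token-mode Welch t matches the closed form and its oracle", {
  r <- welch_t(count1 = 5, n1 = 100, count2 = 1, n2 = 200)
  # hand-evaluated: 0.045 / sqrt(0.05*0.95/100 + 0.005*0.995/200)
  expect_equal(r$t, 0.045 / sqrt(0.000475 + 0.0000248750), tolerance = 1e-10)
  expect_equal(round(r$t, 3), 2.013)
  expect_equal(r$t, oracle_welch_token(5, 100, 1, 200), tolerance = 1e-12)
  expect_lt(r$p, 0.05)

  # equal frequencies give t = 0 with upper-tail p = 0.5
  r0 <- welch_t(10, 100, 20, 200)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)

  # antisymmetry under corpus swap
  ra <- welch_t(7, 120, 2, 340)
  rb <- welch_t(2, 340, 7, 120)
  expect_equal(ra$t, -rb$t)
  expect_error(welch_t(1, 0, 1, 10), "zero-length")
})

test_that("degenerate variances are handled by sign convention", {
  # both sides constant and equal: t = 0; constant but different: +/-Inf
  same <- welch_t(5, 5, 8, 8)        # x1 = x2 = 1
  expect_equal(same$t, 0)
  diffr <- welch_t(5, 5, 0, 8)       # x1 = 1, x2 = 0
  expect_equal(diffr$t, Inf)
  expect_equal(diffr$p, 0)
  expect_equal(welch_t(0, 5, 8, 8)$t, -Inf)
  expect_equal(welch_t(0, 5, 8, 8)$p, 1)
})

test_that("text-mode Welch t agrees with stats::t.test on per-text frequencies", {
  withr::with_seed(21, {
    for (i in 1:20) {
      f1 <- round(runif(sample(3:12, 1)), 3)
      f2 <- round(runif(sample(3:12, 1)), 3)
      mine <- welch_t(NA, length(f1), NA, length(f2), mode = "text",
                      per_text_freqs1 = f1, per_text_freqs2 = f2)
      ref <- stats::t.test(f1, f2, alternative = "greater")
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("bh_retain implements the step-up rule", {
  expect_equal(bh_retain(c(0.01, 0.02, 0.04, 0.05), 0.05), 4L)
  expect_equal(bh_retain(1.0, 0.049), 0L)
  expect_equal(bh_retain(numeric(), 0.05), 0L)
  expect_equal(bh_retain(c(0.001, 0.5, 0.9), 0.05), 1L)
  # a late passer rescues everything before it (step-up, not step-down)
  expect_equal(bh_retain(c(0.04, 0.041, 0.042), 0.05), 3L)
  expect_error(bh_retain(c(0.5, 0.1), 0.05), "sorted")
  expect_error(bh_retain(c(-0.1, 0.5), 0.05), "\\[0, 1\\]")
  # agreement with stats::p.adjust on random tables
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- sort(runif(sample.int(50, 1)))
      k <- bh_retain(p, 0.05)
      expect_equal(k, sum(stats::p.adjust(p, "BH") <= 0.05))
    }
  })
})

test_that("compare_corpora ranks, flags and retains deterministically", {
  S <- build_corpus("S", c("s1", "s2"),
                    list(rep(c("appetite", "filler"), c(6, 4)),
                         rep(c("appetite", "other"), c(5, 5))))
  T_ <- build_corpus("T", c("t1", "t2"),
                     list(rep(c("filler", "other"), c(10, 10)),
                          c("appetite", rep("filler", 19))))
  res <- compare_corpora(S, T_, test_config(t_threshold = 1.73))
  expect_s3_class(res, "corpus_comparison")
  tab <- res$table
  expect_equal(tab$word[1], "appetite")
  expect_true(all(tab$retained == (tab$significant & tab$retained)))
  expect_true(all(tab$t[tab$retained] > 1.73))
  expect_true(!is.unsorted(tab$p))
  expect_true(all(sign(tab$t) == sign(tab$x1 - tab$x2)))
  # identical corpus contents under fresh ids: all t = 0, nothing retained
  dup <- build_corpus("D", c("d1", "d2"),
                      list(rep(c("appetite", "filler"), c(6, 4)),
                           rep(c("appetite", "other"), c(5, 5))))
  S2 <- build_corpus("S2", c("x1", "x2"),
                     list(rep(c("appetite", "filler"), c(6, 4)),
                          rep(c("appetite", "other"), c(5, 5))))
  same <- compare_corpora(S2, dup)
  expect_true(all(same$table$t == 0))
  expect_length(same$keywords, 0L)
  # contract violation: overlapping post ids
  expect_error(compare_corpora(S, build_corpus("X", "s1", list(c("abc")))),
               "share post ids")
})

test_that("comparison tables are antisymmetric under corpus swap", {
  withr::with_seed(17, {
    for (i in 1:10) {
      A <- random_tiny_corpus("a")
      B <- random_tiny_corpus("b")
      ab <- compare_corpora(A, B)$table
      ba <- compare_corpora(B, A)$table
      m <- match(ab$word, ba$word)
      expect_equal(ab$t, -ba$t[m], tolerance = 1e-12)
    }
  })
})

test_that("BH retention is monotone in q and consistent across scopes", {
  S <- withr::with_seed(41, random_tiny_corpus("s", 5, 40))
  T_ <- withr::with_seed(42, random_tiny_corpus("t", 5, 40))
  retained_at <- function(q, scope) {
    cfg <- test_config(bh_q = q, bh_scope = scope)
    compare_corpora(S, T_, cfg)$keywords
  }
  for (scope in c("significant_only", "all_words")) {
    r01 <- retained_at(0.01, scope)
    r05 <- retained_at(0.05, scope)
    r10 <- retained_at(0.10, scope)
    expect_true(all(r01 %in% r05))
    expect_true(all(r05 %in% r10))
  }
})

test_that("min_total_count floors the tested vocabulary", {
  S <- build_corpus("S", "s1", list(c("aaa", "aaa", "bbb")))
  T_ <- build_corpus("T", "t1", list(c("aaa", "ccc")))
  res <- compare_corpora(S, T_, test_config(min_total_count = 2))
  expect_setequal(res$table$word, "aaa")
})

test_that("comparison TSV output is stable and complete", {
  S <- withr::with_seed(51, random_tiny_corpus("s", 4, 30))
  T_ <- withr::with_seed(52, random_tiny_corpus("t", 4, 30))
  res <- compare_corpora(S, T_)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(res, f1)
  write_comparison(res, f2, sidecar = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".meta.json")))
  tab <- read.delim(f1)
  expect_equal(nrow(tab), nrow(res$table))
  meta <- jsonlite::fromJSON(paste0(f1, ".meta.json"))
  expect_equal(meta$n_words_tested, nrow(res$table))
})
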