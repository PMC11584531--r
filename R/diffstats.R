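#' Configuration of the differential word-frequency test
#'
#' @param mode Sampling-unit mode. `"token"` (default) treats each token
#'   position as a Bernoulli trial for the word, so `n` is the corpus
#'   token total and the variance is `x(1-x)`; `"text"` treats each post
#'   as a sampling unit and uses the unbiased sample variance of per-text
#'   relative frequencies, which is robust to bursty words.
#' @param t_threshold Significance cutoff on the one-tailed Welch t
#'   statistic (default 1.73). The significance decision uses this
#'   constant directly; p-values are computed for ranking and
#'   Benjamini-Hochberg retention.
#' @param bh_q Benjamini-Hochberg false-discovery-rate level (default 0.05).
#' @param bh_scope `"significant_only"` (default) applies the BH step-up
#'   rule to the ranked list of already-significant words — the two-stage
#'   procedure this pipeline replicates. Because the largest significant
#'   p-value under this pre-selection is about P(t > 1.73) ~ 0.042 < q,
#'   the two-stage rule retains essentially every significant word; use
#'   `"all_words"` for the statistically standard alternative, where BH
#'   runs over the full vocabulary's p-values and provides real
#'   false-discovery control.
#' @param min_total_count Words whose summed count across the two corpora
#'   is below this floor are not tested (default 1, i.e. no floor).
#' @param min_chars Minimum token length (passed to the tokenizer by
#'   pipeline callers).
#' @return An object of class `test_config`.
#' @export
test_config <- function(mode = c("token", "text"), t_threshold = 1.73,
                        bh_q = 0.05,
                        bh_scope = c("significant_only", "all_words"),
                        min_total_count = 1L, min_chars = 3L) {
  mode <- match.arg(mode)
  bh_scope <- match.arg(bh_scope)
  stopifnot(t_threshold > 0, bh_q > 0, bh_q <= 1, min_total_count >= 1)
  structure(list(mode = mode, t_threshold = t_threshold, bh_q = bh_q,
                 bh_scope = bh_scope,
                 min_total_count = as.integer(min_total_count),
                 min_chars = as.integer(min_chars)),
            class = "test_config")
}

#' @export
print.test_config <- function(x, ...) {
  cat(sprintf(paste0("<test_config> mode=%s, t_threshold=%g, bh_q=%g, ",
                     "bh_scope=%s, min_total_count=%d\n"),
              x$mode, x$t_threshold, x$bh_q, x$bh_scope, x$min_total_count))
  invisible(x)
}

# Vectorized Welch t core. Returns list(t, df, p) given means, variance
# estimates and sampling-unit counts for both sides. Degenerate case
# var1 = var2 = 0: t = 0 when the means agree, +/-Inf otherwise.
welch_core <- function(x1, v1, n1, x2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  diff <- x1 - x2
  t <- ifelse(se2 > 0, diff / sqrt(se2),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) +
                        (v2 / n2)^2 / pmax(n2 - 1, 1)),
               Inf)
  p <- ifelse(is.finite(t), stats::pt(t, df, lower.tail = FALSE),
              ifelse(t > 0, 0, 1))
  p[t == 0] <- 0.5
  list(t = t, df = df, p = p)
}

#' Per-word Welch t statistic between two corpora
#'
#' In token mode the word's mean frequency in corpus i is
#' `x_i = count_i / n_i` over the `n_i` token positions, with Bernoulli
#' indicator variance `x_i (1 - x_i)`, and
#' `t = (x_1 - x_2) / sqrt(var_1/n_1 + var_2/n_2)`. In text mode the
#' sampling units are posts: means and unbiased sample variances are taken
#' over per-text relative frequencies and `n_i` is the number of texts.
#' The p-value is the upper-tail probability under the
#' Welch-Satterthwaite degrees of freedom; `t > 0` means the word is more
#' frequent in the first corpus.
#'
#' @param count1,count2 Occurrences of the word in each corpus
#'   (token mode).
#' @param n1,n2 Total tokens per corpus (token mode) or number of texts
#'   (text mode).
#' @param mode `"token"` or `"text"`.
#' @param per_text_freqs1,per_text_freqs2 Text mode only: numeric vectors
#'   of the word's per-text relative frequencies (lengths `n1`, `n2`,
#'   including zeros).
#' @return List with components `t`, `df`, `p`.
#' @examples
#' welch_t(count1 = 5, n1 = 100, count2 = 1, n2 = 200)$t  # ~2.013
#' @export
welch_t <- function(count1, n1, count2, n2, mode = c("token", "text"),
                    per_text_freqs1 = NULL, per_text_freqs2 = NULL) {
  mode <- match.arg(mode)
  if (any(n1 <= 0) || any(n2 <= 0)) stop("zero-length corpus")
  if (mode == "token") {
    x1 <- count1 / n1
    x2 <- count2 / n2
    welch_core(x1, x1 * (1 - x1), n1, x2, x2 * (1 - x2), n2)
  } else {
    if (is.null(per_text_freqs1) || is.null(per_text_freqs2))
      stop("text mode requires per-text frequency vectors")
    if (length(per_text_freqs1) != n1 || length(per_text_freqs2) != n2)
      stop("per-text frequency vectors must have lengths n1 and n2")
    welch_core(mean(per_text_freqs1), stats::var(per_text_freqs1), n1,
               mean(per_text_freqs2), stats::var(per_text_freqs2), n2)
  }
}

#' Benjamini-Hochberg step-up retention count
#'
#' Given p-values sorted ascending, returns the largest rank `k` such that
#' `p_(k) <= k * q / m` (0 if none); the words at ranks `1..k` are
#' retained.
#'
#' @param p_values Numeric vector, sorted ascending, values in \[0, 1\].
#' @param q False-discovery-rate level.
#' @return Integer retention count `k`.
#' @examples
#' bh_retain(c(0.01, 0.02, 0.04, 0.05), 0.05)  # 4
#' @export
bh_retain <- function(p_values, q) {
  if (!length(p_values)) return(0L)
  if (is.unsorted(p_values)) stop("p_values must be sorted ascending")
  if (any(p_values < 0 | p_values > 1)) stop("p_values must lie in [0, 1]")
  m <- length(p_values)
  ok <- which(p_values <= seq_len(m) * q / m)
  if (length(ok)) max(ok) else 0L
}

# Per-text frequency sum and sum of squares for every word of `vocab`
# (positions aligned with vocab), from a token_corpus.
text_freq_moments <- function(corpus, vocab) {
  s <- numeric(length(vocab))
  s2 <- numeric(length(vocab))
  if (nrow(corpus$cells)) {
    f <- corpus$cells$count / corpus$lengths[corpus$cells$text_idx]
    pos <- match(corpus$vocab[corpus$cells$word_idx], vocab)
    sum1 <- rowsum(f, pos)
    sum2 <- rowsum(f^2, pos)
    idx <- as.integer(rownames(sum1))
    s[idx] <- sum1[, 1L]
    s2[idx] <- sum2[, 1L]
  }
  list(sum = s, sumsq = s2)
}

#' Differential word-frequency comparison of two corpora
#'
#' The package's central procedure: for every word of the union vocabulary
#' (with total count at least `config$min_total_count`), a one-tailed
#' Welch t-test of whether the word is more frequent in corpus `S` than in
#' corpus `T`. Words with `t > config$t_threshold` are significant; the
#' significant words are ranked by ascending p-value and the
#' Benjamini-Hochberg step-up rule decides which are retained as candidate
#' keywords (see [test_config()] for the two BH scopes). Ties in p-value
#' are broken by descending t, then alphabetically, so output order is
#' deterministic.
#'
#' @param S,T `token_corpus` objects built from disjoint post sets (use
#'   [remove_shared()] upstream for drug-vs-drug comparisons).
#' @param config A [test_config()].
#' @param meta Optional named list stored in the result (seed provenance
#'   etc.).
#' @return An object of class `corpus_comparison`: list with `label_s`,
#'   `label_t`, `n1`, `n2` (sampling-unit totals in the chosen mode),
#'   `n_texts_s`, `n_texts_t`, `table` (per-word data frame sorted by
#'   rank: word, count1, count2, x1, x2, t, df, p, significant, retained),
#'   `keywords` (retained words in rank order), `config`, `meta`.
#' @export
compare_corpora <- function(S, T, config = test_config(), meta = list()) {
  stopifnot(inherits(S, "token_corpus"), inherits(T, "token_corpus"),
            inherits(config, "test_config"))
  if (!length(S$post_ids) || !length(T$post_ids))
    stop("zero-length corpus: both corpora must contain at least one text")
  if (length(intersect(S$post_ids, T$post_ids)))
    stop("corpora share post ids; apply remove_shared() upstream")
  if (S$total_tokens == 0 || T$total_tokens == 0)
    stop("zero-length corpus: no tokens after filtering")

  vocab <- sort(unique(c(S$vocab, T$vocab)))
  c1 <- integer(length(vocab))
  c2 <- integer(length(vocab))
  c1[match(S$vocab, vocab)] <- S$vocab_counts
  c2[match(T$vocab, vocab)] <- T$vocab_counts
  keep <- (c1 + c2) >= config$min_total_count
  vocab <- vocab[keep]; c1 <- c1[keep]; c2 <- c2[keep]

  if (config$mode == "token") {
    n1 <- S$total_tokens
    n2 <- T$total_tokens
    x1 <- c1 / n1
    x2 <- c2 / n2
    w <- welch_core(x1, x1 * (1 - x1), n1, x2, x2 * (1 - x2), n2)
  } else {
    n1 <- length(S$post_ids)
    n2 <- length(T$post_ids)
    m1 <- text_freq_moments(S, vocab)
    m2 <- text_freq_moments(T, vocab)
    x1 <- m1$sum / n1
    x2 <- m2$sum / n2
    v1 <- pmax((m1$sumsq - n1 * x1^2) / (n1 - 1), 0)
    v2 <- pmax((m2$sumsq - n2 * x2^2) / (n2 - 1), 0)
    w <- welch_core(x1, v1, n1, x2, v2, n2)
  }

  tab <- data.frame(word = vocab, count1 = c1, count2 = c2,
                    x1 = x1, x2 = x2, t = w$t, df = w$df, p = w$p,
                    significant = w$t > config$t_threshold,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, -tab$t, tab$word), , drop = FALSE]
  rownames(tab) <- NULL

  tab$retained <- FALSE
  if (config$bh_scope == "significant_only") {
    sig_rows <- which(tab$significant)   # already in ascending-p order
    k <- bh_retain(tab$p[sig_rows], config$bh_q)
    if (k > 0L) tab$retained[sig_rows[seq_len(k)]] <- TRUE
  } else {
    k <- bh_retain(tab$p, config$bh_q)
    if (k > 0L) tab$retained <- tab$significant & seq_len(nrow(tab)) <= k
  }

  structure(list(label_s = S$label, label_t = T$label,
                 n1 = n1, n2 = n2,
                 n_texts_s = length(S$post_ids),
                 n_texts_t = length(T$post_ids),
                 table = tab,
                 keywords = tab$word[tab$retained],
                 config = config, meta = meta),
            class = "corpus_comparison")
}

#' @export
print.corpus_comparison <- function(x, ...) {
  cat(sprintf("<corpus_comparison> %s vs %s (%s mode)\n",
              x$label_s, x$label_t, x$config$mode))
  cat(sprintf("  sampling units: n1=%d, n2=%d (%d vs %d texts)\n",
              x$n1, x$n2, x$n_texts_s, x$n_texts_t))
  cat(sprintf("  words tested: %d; significant (t > %g): %d; retained: %d\n",
              nrow(x$table), x$config$t_threshold,
              sum(x$table$significant), length(x$keywords)))
  if (length(x$keywords)) {
    shown <- utils::head(x$keywords, 12L)
    cat("  top keywords:", paste(shown, collapse = ", "),
        if (length(x$keywords) > length(shown)) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.corpus_comparison <- function(object, n = 20L, ...) {
  print(object)
  cat("\nTop of the ranked word table:\n")
  print(utils::head(object$table[, c("word", "count1", "count2", "x1", "x2",
                                     "t", "p", "significant", "retained")],
                    n), digits = 4)
  invisible(object$table)
}

#' @export
as.data.frame.corpus_comparison <- function(x, ...) x$table

#' Keyword-rank plot for a corpus comparison
#'
#' Plots -log10(p) against p-value rank for the tested words, marking the
#' significance threshold region and filling the retained keywords.
#'
#' @param x A `corpus_comparison`.
#' @param max_rank Ranks shown (default 200).
#' @param ... Passed to [plot()].
#' @export
plot.corpus_comparison <- function(x, max_rank = 200L, ...) {
  tab <- utils::head(x$table, max_rank)
  lp <- -log10(pmax(tab$p, 1e-300))
  plot(seq_len(nrow(tab)), lp, type = "p",
       pch = ifelse(tab$retained, 19, 1),
       col = ifelse(tab$retained, "firebrick", "grey40"),
       xlab = "p-value rank", ylab = expression(-log[10](p)),
       main = sprintf("%s vs %s", x$label_s, x$label_t), ...)
  graphics::legend("topright", pch = c(19, 1),
                   col = c("firebrick", "grey40"),
                   legend = c("retained", "not retained"), bty = "n")
  invisible(x)
}

#' Write a comparison result as TSV (plus JSON metadata sidecar)
#'
#' The TSV has columns word, count1, count2, x1, x2, t, p, significant,
#' retained, in rank order, with fixed numeric formatting so identical
#' results are byte-identical on disk. The sidecar `<path>.meta.json`
#' records labels, corpus sizes, the test configuration and any metadata.
#'
#' @param result A `corpus_comparison`.
#' @param path Output TSV path.
#' @param sidecar Write the JSON sidecar too? (default `TRUE`)
#' @return `path`, invisibly.
#' @export
write_comparison <- function(result, path, sidecar = TRUE) {
  tab <- result$table
  fmt <- function(v) sprintf("%.10g", v)
  out <- data.frame(word = tab$word, count1 = tab$count1,
                    count2 = tab$count2, x1 = fmt(tab$x1), x2 = fmt(tab$x2),
                    t = fmt(tab$t), p = fmt(tab$p),
                    significant = tab$significant, retained = tab$retained,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- list(label_s = result$label_s, label_t = result$label_t,
                 n1 = result$n1, n2 = result$n2,
                 n_texts_s = result$n_texts_s, n_texts_t = result$n_texts_t,
                 n_words_tested = nrow(tab),
                 n_significant = sum(tab$significant),
                 n_retained = length(result$keywords),
                 config = unclass(result$config), meta = result$meta)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                                null = "null", digits = NA),
               paste0(path, ".meta.json"))
  }
  invisible(path)
}
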