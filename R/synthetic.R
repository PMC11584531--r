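#' Configuration of the synthetic post-collection generator
#'
#' Describes a synthetic social-media corpus with the statistical
#' structure the differential-frequency analysis assumes: a Zipf-like
#' background vocabulary, negative-binomial post lengths, per-drug mention
#' prevalences, and optional planted signal words whose per-token rate is
#' multiplied by a rate ratio inside the posts mentioning a given drug
#' (emulating an adverse-event word discussed disproportionately by users
#' of that drug).
#'
#' @param n_posts Number of posts to generate.
#' @param vocab_size Background vocabulary size (default 5000).
#' @param zipf_exponent Zipf exponent `s` of the background word
#'   distribution, `p_rank ~ rank^-s` (default 1.05).
#' @param post_length_mean,post_length_dispersion Mean and dispersion
#'   (negative-binomial `mu` and `size`) of the post token count before
#'   drug-synonym insertion; lengths are floored at 3 tokens (defaults 50
#'   and 1.2 — short, strongly overdispersed forum posts).
#' @param drug_prevalence Named numeric vector: canonical drug name ->
#'   probability that a post mentions the drug (independent across drugs
#'   and posts).
#' @param planted_signals List of planted signals, each a list with
#'   `drug`, `word`, `rate_ratio`, and optional `base_rank` (default 300):
#'   inside posts mentioning `drug`, `word`'s per-token rate is its
#'   background rate times `rate_ratio`. A word not in the background
#'   vocabulary is added at the Zipf probability of `base_rank`.
#' @param burstiness Dirichlet-multinomial concentration; `Inf` (default)
#'   disables burstiness, finite values draw a per-text topic weighting
#'   `theta ~ Dirichlet(burstiness * p)` so words clump within texts
#'   (intended for small stress-test configurations; it is O(n_posts *
#'   vocab_size)).
#' @param lexicon `drug_lexicon` supplying the synonyms inserted for
#'   mentioned drugs.
#' @param date_range Length-2 epoch-second vector; timestamps are uniform
#'   over `[start, end)` (default 2010-01-01 to 2020-01-01 UTC).
#' @param seed Integer seed; generation is bit-reproducible given the
#'   config.
#' @return An object of class `synth_config`.
#' @seealso [synth_config_paper_like()] for the study-scale preset.
#' @export
synth_config <- function(n_posts, vocab_size = 5000L, zipf_exponent = 1.05,
                         post_length_mean = 50, post_length_dispersion = 1.2,
                         drug_prevalence = numeric(),
                         planted_signals = list(),
                         burstiness = Inf,
                         lexicon = default_lexicon(),
                         date_range = c(1262304000, 1577836800),
                         seed = 1L) {
  stopifnot(n_posts >= 1, vocab_size >= 10, zipf_exponent > 0,
            post_length_mean > 0, post_length_dispersion > 0,
            burstiness > 0, length(date_range) == 2L,
            date_range[1] < date_range[2])
  if (length(drug_prevalence)) {
    stopifnot(!is.null(names(drug_prevalence)),
              all(drug_prevalence >= 0), all(drug_prevalence <= 1))
    unknown <- setdiff(names(drug_prevalence), names(lexicon$entries))
    if (length(unknown)) stop("drug_prevalence names not in lexicon: ",
                              paste(unknown, collapse = ", "))
  }
  planted_signals <- lapply(planted_signals, function(sig) {
    sig <- as.list(sig)
    stopifnot(!is.null(sig$drug), !is.null(sig$word), !is.null(sig$rate_ratio))
    sig$rate_ratio <- as.numeric(sig$rate_ratio)
    if (sig$rate_ratio < 0) stop("rate_ratio must be >= 0")
    if (!sig$drug %in% names(drug_prevalence))
      stop("planted signal references a drug without a prevalence: ", sig$drug)
    if (grepl("[^[:alpha:]]", sig$word) || nchar(sig$word) < 3L)
      stop("planted word must be >= 3 letters: ", sig$word)
    sig$base_rank <- as.integer(sig$base_rank %||% 300L)
    stopifnot(sig$base_rank >= 1L, sig$base_rank <= vocab_size)
    sig
  })
  structure(list(n_posts = as.integer(n_posts),
                 vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 post_length_mean = post_length_mean,
                 post_length_dispersion = post_length_dispersion,
                 drug_prevalence = drug_prevalence,
                 planted_signals = planted_signals,
                 burstiness = burstiness,
                 lexicon = lexicon,
                 date_range = as.numeric(date_range),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Study-scale synthetic preset
#'
#' A collection shaped like a decade of posts from a migraine support
#' forum: 22,467 posts with drug-mention prevalences 1.79% (propranolol),
#' 6.33% (topiramate), 2.08% (erenumab) and 0.32% (fremanezumab), so a
#' run reproduces the corpus-size structure the analysis was designed
#' around (including the small fremanezumab corpus of ~73 posts).
#'
#' @param seed Integer seed.
#' @param planted_signals Passed to [synth_config()] (default none: the
#'   null model).
#' @param ... Further overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_paper_like <- function(seed = 1L, planted_signals = list(), ...) {
  synth_config(n_posts = 22467L,
               drug_prevalence = c(propranolol = 0.0179,
                                   topiramate = 0.0633,
                                   erenumab = 0.0208,
                                   fremanezumab = 0.0032),
               planted_signals = planted_signals,
               seed = seed, ...)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d posts, vocab %d (zipf %g), ",
                     "length NB(mu=%g, size=%g), seed %d\n"),
              x$n_posts, x$vocab_size, x$zipf_exponent, x$post_length_mean,
              x$post_length_dispersion, x$seed))
  if (length(x$drug_prevalence)) {
    cat("  prevalences:",
        paste(sprintf("%s=%.4f", names(x$drug_prevalence), x$drug_prevalence),
              collapse = ", "), "\n")
  }
  for (sig in x$planted_signals)
    cat(sprintf("  planted: '%s' x%g in %s posts (base rank %d)\n",
                sig$word, sig$rate_ratio, sig$drug, sig$base_rank))
  invisible(x)
}

# Deterministic synthetic vocabulary: "w" + fixed-width base-26 index,
# so every word is >= 4 letters and survives the tokenizer.
synth_vocab <- function(vocab_size) {
  width <- max(3L, ceiling(log(vocab_size + 1) / log(26)))
  idx <- seq_len(vocab_size) - 1L
  mat <- matrix("", nrow = vocab_size, ncol = width)
  for (j in seq_len(width)) {
    mat[, width - j + 1L] <- letters[(idx %% 26L) + 1L]
    idx <- idx %/% 26L
  }
  paste0("w", apply(mat, 1L, paste0, collapse = ""))
}

#' Generate a synthetic post collection
#'
#' Samples the collection described by a [synth_config()]: per-post drug
#' mentions (independent Bernoulli per drug), negative-binomial token
#' counts, Zipf background tokens with planted-signal rates multiplied
#' inside mentioning posts, one randomly chosen synonym of each mentioned
#' drug inserted at a random position, and the first up-to-8 tokens used
#' as the title with the rest as the body.
#'
#' @param config A `synth_config`.
#' @return A `post_collection` (see [load_posts()]) with the generating
#'   config in `attr(, "config")` and the per-drug planted words in
#'   `attr(, "planted")`.
#' @export
generate_posts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_posts_impl(config))
}

generate_posts_impl <- function(config) {
  n <- config$n_posts
  vocab <- synth_vocab(config$vocab_size)
  wt <- seq_len(config$vocab_size)^(-config$zipf_exponent)

  # planted words not in the background vocabulary enter at base_rank's weight
  planted_words <- vapply(config$planted_signals, `[[`, "", "word")
  for (sig in config$planted_signals) {
    if (!sig$word %in% vocab) {
      vocab <- c(vocab, sig$word)
      wt <- c(wt, sig$base_rank^(-config$zipf_exponent))
    }
  }
  prob <- wt / sum(wt)
  n_words <- length(vocab)

  drugs <- names(config$drug_prevalence)
  mention <- matrix(FALSE, nrow = n, ncol = length(drugs),
                    dimnames = list(NULL, drugs))
  for (d in drugs)
    mention[, d] <- stats::runif(n) < config$drug_prevalence[[d]]

  lens <- pmax(stats::rnbinom(n, size = config$post_length_dispersion,
                              mu = config$post_length_mean), 3L)

  # per-post signature = which signal-bearing drugs it mentions; posts with
  # the same signature share a token distribution and are sampled in bulk
  sig_drugs <- unique(vapply(config$planted_signals, `[[`, "", "drug"))
  sig_drugs <- sig_drugs[vapply(sig_drugs, function(d) {
    any(vapply(config$planted_signals,
               function(s) s$drug == d && s$rate_ratio != 1, TRUE))
  }, TRUE)]
  signature <- rep(0L, n)
  if (length(sig_drugs)) {
    for (j in seq_along(sig_drugs))
      signature <- signature + as.integer(mention[, sig_drugs[j]]) * 2L^(j - 1L)
  }

  sig_prob <- function(s) {
    pv <- prob
    if (s > 0L) {
      on_drugs <- sig_drugs[bitwAnd(s, 2L^(seq_along(sig_drugs) - 1L)) > 0L]
      for (sg in config$planted_signals) {
        if (sg$drug %in% on_drugs)
          pv[match(sg$word, vocab)] <- pv[match(sg$word, vocab)] * sg$rate_ratio
      }
      pv <- pv / sum(pv)
    }
    pv
  }

  tokens <- character(sum(lens))
  post_of <- rep.int(seq_len(n), lens)
  if (is.finite(config$burstiness)) {
    # per-text Dirichlet-multinomial draw (small configs only)
    start <- cumsum(c(1L, lens))[seq_len(n)]
    for (i in seq_len(n)) {
      pv <- sig_prob(signature[i])
      theta <- stats::rgamma(n_words, shape = config$burstiness * pv)
      if (sum(theta) == 0) theta <- pv
      tokens[start[i] + seq_len(lens[i]) - 1L] <-
        vocab[sample.int(n_words, lens[i], replace = TRUE, prob = theta)]
    }
  } else {
    for (s in sort(unique(signature))) {
      rows <- which(signature == s)
      total <- sum(lens[rows])
      tokens[post_of %in% rows] <-
        vocab[sample.int(n_words, total, replace = TRUE, prob = sig_prob(s))]
    }
  }
  # title = first up-to-8 tokens, rest body; assembled by character offsets
  # into one collapsed string (avoids materializing 1 list per post)
  end_tok <- cumsum(lens)
  start_tok <- end_tok - lens + 1L
  nch <- nchar(tokens)
  cum <- cumsum(nch + 1L)
  tok_end <- cum - 1L
  tok_start <- cum - nch
  big <- paste(tokens, collapse = " ")
  ntitle <- pmin(lens, 8L)
  title <- substring(big, tok_start[start_tok],
                     tok_end[start_tok + ntitle - 1L])
  body <- character(n)
  hasb <- lens > 8L
  body[hasb] <- substring(big, tok_start[start_tok[hasb] + 8L],
                          tok_end[end_tok[hasb]])

  # insert one synonym of each mentioned drug at a random position
  mention_rows <- which(rowSums(mention) > 0)
  for (i in mention_rows) {
    tok <- tokens[start_tok[i]:end_tok[i]]
    for (d in drugs[mention[i, ]]) {
      syns <- config$lexicon$entries[[d]]
      syn <- syns[sample.int(length(syns), 1L)]
      pos <- sample.int(length(tok) + 1L, 1L)
      tok <- append(tok, syn, after = pos - 1L)
    }
    title[i] <- paste(utils::head(tok, 8L), collapse = " ")
    body[i] <- paste(utils::tail(tok, -8L), collapse = " ")
  }

  span <- config$date_range
  ts <- floor(span[1] + stats::runif(n) * (span[2] - span[1]))

  out <- data.frame(post_id = sprintf("syn%06d", seq_len(n)),
                    timestamp = ts, title = title, body = body,
                    stringsAsFactors = FALSE)
  out$text <- normalize_post_text(out$title, out$body)
  class(out) <- c("post_collection", "data.frame")
  planted <- split(planted_words,
                   vapply(config$planted_signals, `[[`, "", "drug"))
  attr(out, "config") <- config
  attr(out, "planted") <- planted
  out
}

#' Recovery metrics for planted signal words
#'
#' Scores how well a comparison's retained keyword list recovers the
#' words planted in the generator: recall is the fraction of planted
#' words retained, precision the fraction of retained words that were
#' planted (1 when both sets are empty; `NA` when nothing was retained
#' but signals were planted), and the false-flag rate is the fraction of
#' non-planted tested words that were retained.
#'
#' @param result A `corpus_comparison`.
#' @param planted_words Character vector of planted words for this
#'   comparison's direction.
#' @return An object of class `recovery_metrics`: list with `recall`,
#'   `precision`, `false_flag_rate`, `n_planted`, `n_retained`.
#' @export
score_recovery <- function(result, planted_words) {
  planted_words <- unique(as.character(planted_words))
  retained <- result$keywords
  tested <- result$table$word
  hit <- intersect(retained, planted_words)
  recall <- if (!length(planted_words)) 1 else length(hit) / length(planted_words)
  precision <- if (!length(retained)) {
    if (!length(planted_words)) 1 else NA_real_
  } else length(hit) / length(retained)
  n_nonplanted <- sum(!tested %in% planted_words)
  ffr <- if (n_nonplanted == 0) 0 else
    length(setdiff(retained, planted_words)) / n_nonplanted
  structure(list(recall = recall, precision = precision,
                 false_flag_rate = ffr,
                 n_planted = length(planted_words),
                 n_retained = length(retained)),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(paste0("<recovery_metrics> recall %.3f, precision %s, ",
                     "false-flag rate %.4g (%d planted, %d retained)\n"),
              x$recall,
              if (is.na(x$precision)) "NA" else sprintf("%.3f", x$precision),
              x$false_flag_rate, x$n_planted, x$n_retained))
  invisible(x)
}
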