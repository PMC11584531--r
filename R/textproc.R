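#' Tokenize normalized text
#'
#' Splits on maximal runs of non-letter characters — digits, punctuation
#' and symbols all act as separators, not merely as characters to strip —
#' then discards tokens shorter than `min_chars` letters. "50mg" therefore
#' yields only "mg" (dropped), never the pseudo-word "mg50"; apostrophes
#' split contractions ("didn't" -> "didn"). No stemming, stop-word removal
#' or spelling correction is applied: the analysis works on raw surface
#' forms.
#'
#' @param text Character vector of normalized (lowercase) texts.
#' @param min_chars Minimum token length kept (default 3).
#' @return For a single string, a character vector of tokens in order; for
#'   a vector, a list of such vectors.
#' @examples
#' tokenize("topamax 50mg made me so foggy!!")
#' @export
tokenize <- function(text, min_chars = 3L) {
  out <- lapply(strsplit(as.character(text), "[^[:alpha:]]+"), function(tok) {
    tok[nchar(tok) >= min_chars]
  })
  if (length(text) == 1L) out[[1L]] else out
}

#' Build a corpus of tokenized texts
#'
#' Aggregates per-text token lists into the count structures the
#' differential test needs: total token count, corpus-wide word counts,
#' and the per-text count triplets used by the text-level sampling mode.
#'
#' @param label Corpus label (e.g. the drug name).
#' @param post_ids Character vector of unique text identifiers.
#' @param token_lists List of character vectors, one per post, aligned
#'   with `post_ids` (as returned by [tokenize()] on several texts).
#' @return An object of class `token_corpus`: list with `label`,
#'   `post_ids`, `lengths` (token count per text), `total_tokens`,
#'   `vocab` (sorted), `vocab_counts` (named integer, same order), and
#'   `cells` (data frame `word_idx`, `text_idx`, `count` of the non-zero
#'   per-text counts).
#' @export
build_corpus <- function(label, post_ids, token_lists) {
  post_ids <- as.character(post_ids)
  stopifnot(length(post_ids) == length(token_lists))
  if (anyDuplicated(post_ids))
    stop("duplicate post_id in corpus: ", post_ids[duplicated(post_ids)][1L])
  lens <- lengths(token_lists)
  toks <- unlist(token_lists, use.names = FALSE)
  if (is.null(toks)) toks <- character()
  vocab <- sort(unique(toks))
  widx <- match(toks, vocab)
  tidx <- rep.int(seq_along(token_lists), lens)
  if (length(toks)) {
    # count (word, text) pairs via one radix sort + run-length encoding
    ntext1 <- length(token_lists) + 1
    key <- as.numeric(widx) * ntext1 + tidx
    r <- rle(sort(key, method = "radix"))
    cells <- data.frame(
      word_idx = as.integer(r$values %/% ntext1),
      text_idx = as.integer(r$values %% ntext1),
      count = r$lengths
    )
    vocab_counts <- tabulate(widx, nbins = length(vocab))
  } else {
    cells <- data.frame(word_idx = integer(), text_idx = integer(),
                        count = integer())
    vocab_counts <- integer()
  }
  names(vocab_counts) <- vocab
  structure(list(label = as.character(label), post_ids = post_ids,
                 lengths = as.integer(lens),
                 total_tokens = sum(lens),
                 vocab = vocab, vocab_counts = vocab_counts,
                 cells = cells),
            class = "token_corpus")
}

#' Tokenize a subset of posts into a corpus
#'
#' Convenience wrapper: select posts by id, tokenize their normalized
#' text, and build the corpus.
#'
#' @param posts A `post_collection`.
#' @param post_ids Ids of the posts forming the corpus.
#' @param label Corpus label.
#' @param min_chars Minimum token length (see [tokenize()]).
#' @return A `token_corpus`.
#' @export
corpus_from_posts <- function(posts, post_ids, label, min_chars = 3L) {
  idx <- match(post_ids, posts$post_id)
  if (anyNA(idx)) stop("post_id not found in collection: ", post_ids[is.na(idx)][1L])
  build_corpus(label, post_ids, tokenize(posts$text[idx], min_chars))
}

#' @export
print.token_corpus <- function(x, ...) {
  cat(sprintf("<token_corpus> '%s': %d text(s), %d tokens, %d distinct words\n",
              x$label, length(x$post_ids), x$total_tokens, length(x$vocab)))
  invisible(x)
}

#' Export corpus word counts as TSV
#'
#' Writes columns `word`, `count`, `n_texts_containing`.
#' @param corpus A `token_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_counts <- function(corpus, path) {
  n_texts <- tabulate(corpus$cells$word_idx, nbins = length(corpus$vocab))
  df <- data.frame(word = corpus$vocab,
                   count = as.integer(corpus$vocab_counts),
                   n_texts_containing = n_texts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
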