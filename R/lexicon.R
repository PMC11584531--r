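#' Construct a drug lexicon
#'
#' A drug lexicon maps each canonical drug name to a set of lowercase
#' synonyms (brand and generic names) and flags the drugs belonging to the
#' CGRP therapeutic class, which are excluded from the control pool even
#' when they are not study drugs.
#'
#' @param entries Named list: canonical drug name -> character vector of
#'   lowercase synonyms (each at least 3 characters; synonym sets of
#'   different drugs must be disjoint).
#' @param cgrp_class Character vector of canonical names (subset of
#'   `names(entries)`) flagged as CGRP therapeutics.
#' @return An object of class `drug_lexicon`.
#' @seealso [default_lexicon()] for the migraine-preventive lexicon used
#'   throughout the package's examples.
#' @export
drug_lexicon <- function(entries, cgrp_class = character()) {
  stopifnot(is.list(entries), length(entries) > 0L, !is.null(names(entries)))
  entries <- lapply(entries, function(s) unique(as.character(s)))
  for (drug in names(entries)) {
    syn <- entries[[drug]]
    if (!length(syn)) stop("empty synonym set for drug: ", drug)
    if (any(syn != tolower(syn))) stop("synonyms must be lowercase: ", drug)
    if (any(nchar(syn) < 3L)) stop("synonyms must have >= 3 characters: ", drug)
    if (any(grepl("[^[:alpha:]]", syn)))
      stop("synonyms must contain letters only (tokens cannot contain digits or symbols): ", drug)
  }
  all_syn <- unlist(entries, use.names = FALSE)
  if (anyDuplicated(all_syn))
    stop("synonym sets of different drugs must be disjoint: ",
         all_syn[duplicated(all_syn)][1L])
  cgrp_class <- as.character(cgrp_class)
  if (!all(cgrp_class %in% names(entries)))
    stop("cgrp_class must be a subset of lexicon entries")
  structure(list(entries = entries, cgrp_class = cgrp_class),
            class = "drug_lexicon")
}

#' Default migraine-preventive drug lexicon
#'
#' Ships the four study drugs (propranolol, topiramate, erenumab,
#' fremanezumab) with brand/generic synonyms plus the other CGRP
#' monoclonal-antibody therapeutics (galcanezumab, eptinezumab), which are
#' flagged so that posts mentioning them are kept out of the control pool.
#' The common misspelling "propanolol" is included as a propranolol synonym.
#'
#' @return A `drug_lexicon`.
#' @export
default_lexicon <- function() {
  drug_lexicon(
    entries = list(
      propranolol  = c("propranolol", "inderal", "propanolol"),
      topiramate   = c("topiramate", "topamax", "trokendi"),
      erenumab     = c("erenumab", "aimovig"),
      fremanezumab = c("fremanezumab", "ajovy"),
      galcanezumab = c("galcanezumab", "emgality"),
      eptinezumab  = c("eptinezumab", "vyepti")
    ),
    cgrp_class = c("erenumab", "fremanezumab", "galcanezumab", "eptinezumab")
  )
}

#' Read / write a drug lexicon as JSON
#'
#' The file format is a JSON map
#' `{"canonical": {"synonyms": [...], "cgrp": true/false}, ...}`.
#'
#' @param path File path.
#' @return `read_lexicon()` returns a `drug_lexicon`; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  entries <- lapply(raw, function(e) as.character(e$synonyms))
  cgrp <- names(raw)[vapply(raw, function(e) isTRUE(e$cgrp), TRUE)]
  drug_lexicon(entries, cgrp)
}

#' @rdname read_lexicon
#' @param lexicon A `drug_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- lapply(names(lexicon$entries), function(drug) {
    list(synonyms = lexicon$entries[[drug]],
         cgrp = drug %in% lexicon$cgrp_class)
  })
  names(out) <- names(lexicon$entries)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat(sprintf("<drug_lexicon> %d drug(s), %d CGRP-class\n",
              length(x$entries), length(x$cgrp_class)))
  for (drug in names(x$entries)) {
    cat(sprintf("  %s%s: %s\n", drug,
                if (drug %in% x$cgrp_class) " [CGRP]" else "",
                paste(x$entries[[drug]], collapse = ", ")))
  }
  invisible(x)
}

#' Does a post mention a drug?
#'
#' A mention is a whole-token match of any synonym, where token boundaries
#' are maximal runs of letters: "topamax50" does not count as a topamax
#' mention because the tokenizer splits on digits, but "topamax," does.
#'
#' @param post A single post (one row of a `post_collection`) or a
#'   normalized lowercase text string.
#' @param synonyms Non-empty character vector of lowercase synonyms.
#' @return `TRUE` if any synonym occurs as a whole token.
#' @export
mentions_drug <- function(post, synonyms) {
  if (!length(synonyms)) stop("empty synonym set")
  text <- if (is.data.frame(post)) post$text else as.character(post)
  grepl(token_pattern(synonyms), text, perl = TRUE)
}

#' Assemble per-drug corpora and the control pool
#'
#' Each study drug's corpus is the set of posts mentioning any of its
#' synonyms (a post mentioning two study drugs appears in both corpora at
#' this stage; overlap is handled later by [remove_shared()] for pairwise
#' comparisons). The control pool contains the posts that mention no
#' synonym of any study drug and no synonym of any CGRP-class drug.
#'
#' @param posts A `post_collection`.
#' @param lexicon A `drug_lexicon`.
#' @param study_drugs Canonical names of the drugs under study (must exist
#'   in the lexicon).
#' @return An object of class `corpus_assignment`: list with
#'   `drug_corpora` (named list of post_id vectors), `control_pool`
#'   (post_id vector), and `control_groups`/`seed` (populated by
#'   [partition_controls()]).
#' @export
build_corpora <- function(posts, lexicon, study_drugs) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  unknown <- setdiff(study_drugs, names(lexicon$entries))
  if (length(unknown)) stop("unknown drug name(s): ", paste(unknown, collapse = ", "))
  hits <- lapply(study_drugs, function(d)
    mentions_drug(posts$text, lexicon$entries[[d]]))
  names(hits) <- study_drugs
  drug_corpora <- lapply(hits, function(h) posts$post_id[h])
  excluded <- Reduce(`|`, hits, rep(FALSE, nrow(posts)))
  extra <- setdiff(lexicon$cgrp_class, study_drugs)
  if (length(extra)) {
    extra_syn <- unlist(lexicon$entries[extra], use.names = FALSE)
    excluded <- excluded | mentions_drug(posts$text, extra_syn)
  }
  structure(list(drug_corpora = drug_corpora,
                 control_pool = posts$post_id[!excluded],
                 control_groups = NULL,
                 seed = NULL),
            class = "corpus_assignment")
}

#' Randomly partition the control pool into k groups
#'
#' Mirrors assigning each control post an independent uniform random digit
#' in 1..k and grouping by digit; group sizes are therefore
#' multinomial, not balanced. Deterministic given the seed; the caller's
#' RNG state is untouched.
#'
#' @param assignment A `corpus_assignment` (or a character vector of
#'   post ids to partition).
#' @param k Number of groups (>= 1).
#' @param seed Integer seed recorded alongside the partition.
#' @return If given a `corpus_assignment`, the assignment with
#'   `control_groups` (list of k disjoint post_id vectors whose union is
#'   the control pool) and `seed` filled in; if given a vector, the list of
#'   groups with the seed as attribute.
#' @export
partition_controls <- function(assignment, k = 4L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  k <- as.integer(k)
  pool <- if (inherits(assignment, "corpus_assignment")) assignment$control_pool else as.character(assignment)
  digit <- with_seed(seed, sample.int(k, length(pool), replace = TRUE))
  groups <- lapply(seq_len(k), function(i) pool[digit == i])
  if (inherits(assignment, "corpus_assignment")) {
    assignment$control_groups <- groups
    assignment$seed <- as.integer(seed)
    assignment
  } else {
    structure(groups, seed = as.integer(seed))
  }
}

#' Drop posts shared between two corpora
#'
#' A post present in both corpora of a pairwise drug-vs-drug comparison is
#' removed from both sides, so the compared corpora are disjoint.
#'
#' @param corpusA,corpusB Character vectors of post ids.
#' @return List with elements `a`, `b` (the disjoint remainders) and
#'   `removed` (the shared ids).
#' @export
remove_shared <- function(corpusA, corpusB) {
  shared <- intersect(corpusA, corpusB)
  list(a = setdiff(corpusA, shared), b = setdiff(corpusB, shared),
       removed = shared)
}

#' @export
print.corpus_assignment <- function(x, ...) {
  cat("<corpus_assignment>\n")
  for (d in names(x$drug_corpora))
    cat(sprintf("  %-14s %6d post(s)\n", d, length(x$drug_corpora[[d]])))
  cat(sprintf("  %-14s %6d post(s)\n", "control pool", length(x$control_pool)))
  if (!is.null(x$control_groups))
    cat(sprintf("  control groups: %s (seed %d)\n",
                paste(lengths(x$control_groups), collapse = "/"), x$seed))
  invisible(x)
}

#' Persist a corpus assignment as JSON for audit
#' @param assignment A `corpus_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  writeLines(jsonlite::toJSON(unclass(assignment), auto_unbox = TRUE,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}
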