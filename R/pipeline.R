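#' Define a study plan
#'
#' A study plan lists the corpus-pair comparisons to run, how many control
#' groups to draw, the seed for the control partition, and the test
#' configuration. A comparison side is either a canonical drug name from
#' the lexicon or a control-group reference `"group1"`, `"group2"`, ...
#' (index at most `control_k`). Drug-vs-drug comparisons drop posts shared
#' by both corpora; drug-vs-control comparisons use the control group as
#' is (controls by construction mention no study drug).
#'
#' @param comparisons List of comparisons, each a list or character vector
#'   with elements `label`, `s`, `t` (side `s` is the direction in which
#'   higher frequency is flagged).
#' @param control_k Number of control groups (default 4).
#' @param seed Integer seed for the control partition.
#' @param test_config A [test_config()].
#' @param highlight_terms Optional character vector of words (e.g. a
#'   curated adverse-event term list) to flag in reports; the pipeline
#'   never labels a keyword as an adverse event on its own.
#' @param pooling_map Optional named character vector mapping surface
#'   forms to pooled keys (e.g. `c(dizzy = "dizziness")`), applied to
#'   tokens before counting; off (`NULL`) by default.
#' @param study_drugs Canonical drug names whose mentions (together with
#'   the lexicon's CGRP class) are excluded from the control pool. Default
#'   `NULL`: the drugs referenced by the comparisons. Set explicitly when
#'   running a subset of comparisons that should share the full design's
#'   control pool.
#' @return An object of class `study_plan`.
#' @export
study_plan <- function(comparisons = default_comparisons(), control_k = 4L,
                       seed = 1L, test_config = pharmakeyword::test_config(),
                       highlight_terms = NULL, pooling_map = NULL,
                       study_drugs = NULL) {
  stopifnot(control_k >= 1L, inherits(test_config, "test_config"))
  comparisons <- lapply(comparisons, function(cmp) {
    cmp <- as.list(cmp)
    stopifnot(!is.null(cmp$s), !is.null(cmp$t))
    if (is.null(cmp$label)) cmp$label <- paste0(cmp$s, "_vs_", cmp$t)
    cmp[c("label", "s", "t")]
  })
  for (cmp in comparisons) {
    for (side in c(cmp$s, cmp$t)) {
      g <- parse_group_ref(side)
      if (!is.na(g) && g > control_k)
        stop("control group index exceeds control_k: ", side)
    }
  }
  structure(list(comparisons = comparisons, control_k = as.integer(control_k),
                 seed = as.integer(seed), test_config = test_config,
                 highlight_terms = highlight_terms,
                 pooling_map = pooling_map,
                 study_drugs = study_drugs),
            class = "study_plan")
}

#' The default six-comparison study design
#'
#' One drug-vs-drug validation pair (topiramate vs propranolol), two
#' validation drug-vs-control pairs, two application drug-vs-control pairs
#' for the CGRP monoclonal antibodies, and the erenumab-vs-fremanezumab
#' application pair.
#'
#' @return List of comparison descriptors for [study_plan()].
#' @export
default_comparisons <- function() {
  list(
    list(label = "topiramate_vs_propranolol", s = "topiramate", t = "propranolol"),
    list(label = "propranolol_vs_group1", s = "propranolol", t = "group1"),
    list(label = "topiramate_vs_group2", s = "topiramate", t = "group2"),
    list(label = "erenumab_vs_group3", s = "erenumab", t = "group3"),
    list(label = "fremanezumab_vs_group4", s = "fremanezumab", t = "group4"),
    list(label = "erenumab_vs_fremanezumab", s = "erenumab", t = "fremanezumab")
  )
}

parse_group_ref <- function(side) {
  if (grepl("^group[0-9]+$", side)) as.integer(sub("^group", "", side)) else NA_integer_
}

#' @export
print.study_plan <- function(x, ...) {
  cat(sprintf("<study_plan> %d comparison(s), %d control group(s), seed %d\n",
              length(x$comparisons), x$control_k, x$seed))
  for (cmp in x$comparisons)
    cat(sprintf("  %s: %s > %s ?\n", cmp$label, cmp$s, cmp$t))
  print(x$test_config)
  invisible(x)
}

apply_pooling <- function(token_lists, pooling_map) {
  if (is.null(pooling_map)) return(token_lists)
  lapply(token_lists, function(tok) {
    hit <- match(tok, names(pooling_map))
    tok[!is.na(hit)] <- pooling_map[hit[!is.na(hit)]]
    tok
  })
}

#' Run a keyword study end-to-end
#'
#' Executes the full pipeline: assemble per-drug corpora and the control
#' pool from the lexicon, partition controls into groups under the plan's
#' seed, then for each planned comparison tokenize both sides (dropping
#' shared posts for drug-vs-drug pairs), run the differential test, and
#' collect the results. A comparison with an empty side is recorded as
#' failed and the run continues. Deterministic given (posts, lexicon,
#' plan).
#'
#' @param posts A `post_collection`.
#' @param lexicon A `drug_lexicon` (default [default_lexicon()]).
#' @param plan A [study_plan()].
#' @param verbose Log phase sizes and exclusions via [message()]?
#' @return An object of class `keyword_study`: list with `results` (named
#'   list; each element a `corpus_comparison` or a failure record),
#'   `summary` (per-drug post counts and percentages), `assignment`
#'   (the `corpus_assignment` incl. control groups), `plan`, `n_posts`.
#' @export
run_study <- function(posts, lexicon = default_lexicon(),
                      plan = study_plan(), verbose = FALSE) {
  stopifnot(nrow(posts) > 0L)
  say <- function(...) if (verbose) message(sprintf(...))
  drugs <- unique(c(plan$study_drugs,
                    unlist(lapply(plan$comparisons, function(cmp) {
                      side <- c(cmp$s, cmp$t)
                      side[is.na(vapply(side, parse_group_ref, 0L))]
                    }))))
  say("assembling corpora for %d drug(s) over %d posts", length(drugs), nrow(posts))
  assignment <- build_corpora(posts, lexicon, drugs)
  assignment <- partition_controls(assignment, k = plan$control_k,
                                   seed = plan$seed)
  say("control pool %d posts -> groups %s (seed %d)",
      length(assignment$control_pool),
      paste(lengths(assignment$control_groups), collapse = "/"), plan$seed)

  side_ids <- function(side) {
    g <- parse_group_ref(side)
    if (!is.na(g)) assignment$control_groups[[g]] else assignment$drug_corpora[[side]]
  }
  make_corpus <- function(ids, label) {
    idx <- match(ids, posts$post_id)
    toks <- tokenize(posts$text[idx], plan$test_config$min_chars)
    if (length(ids) == 1L) toks <- list(toks)
    toks <- apply_pooling(toks, plan$pooling_map)
    build_corpus(label, ids, toks)
  }

  results <- list()
  for (cmp in plan$comparisons) {
    ids_s <- side_ids(cmp$s)
    ids_t <- side_ids(cmp$t)
    drug_vs_drug <- is.na(parse_group_ref(cmp$s)) && is.na(parse_group_ref(cmp$t))
    n_shared <- 0L
    if (drug_vs_drug) {
      rs <- remove_shared(ids_s, ids_t)
      n_shared <- length(rs$removed)
      ids_s <- rs$a
      ids_t <- rs$b
    }
    say("%s: %d vs %d texts (%d shared removed)", cmp$label,
        length(ids_s), length(ids_t), n_shared)
    if (!length(ids_s) || !length(ids_t)) {
      results[[cmp$label]] <- structure(
        list(label = cmp$label, s = cmp$s, t = cmp$t, failed = TRUE,
             reason = sprintf("empty side: |S|=%d, |T|=%d",
                              length(ids_s), length(ids_t))),
        class = "comparison_failure")
      next
    }
    res <- compare_corpora(make_corpus(ids_s, cmp$s),
                           make_corpus(ids_t, cmp$t),
                           config = plan$test_config,
                           meta = list(label = cmp$label, seed = plan$seed,
                                       shared_removed = n_shared))
    results[[cmp$label]] <- res
  }

  structure(list(results = results,
                 summary = corpus_summary(assignment, nrow(posts)),
                 assignment = assignment, plan = plan,
                 n_posts = nrow(posts)),
            class = "keyword_study")
}

#' Per-drug corpus summary
#'
#' Post counts per drug corpus with the percentage of the total
#' collection, rounded half-up to the requested number of decimals.
#'
#' @param assignment A `corpus_assignment`.
#' @param total_posts Total number of posts in the collection (> 0).
#' @param decimals Decimal places for the percentage (default 2).
#' @return Data frame with columns `drug`, `count`, `percent`.
#' @export
corpus_summary <- function(assignment, total_posts, decimals = 2L) {
  stopifnot(total_posts > 0)
  counts <- lengths(assignment$drug_corpora)
  data.frame(drug = names(assignment$drug_corpora),
             count = as.integer(counts),
             percent = round_half_up(100 * counts / total_posts, decimals),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate retained keywords with a highlight dictionary
#'
#' Flags each retained keyword that appears in a user-supplied term list
#' (for instance a curated adverse-event vocabulary). Only retained words
#' are reported; the pipeline makes no adverse-event judgement itself.
#'
#' @param result A `corpus_comparison`.
#' @param highlight_terms Character vector of terms to flag (may be
#'   `NULL`/empty).
#' @return Data frame with columns `rank`, `keyword`, `flagged`, with the
#'   number of flagged keywords as attribute `n_flagged`.
#' @export
highlight_report <- function(result, highlight_terms = NULL) {
  kw <- result$keywords
  flagged <- if (length(highlight_terms)) kw %in% highlight_terms else rep(FALSE, length(kw))
  out <- data.frame(rank = seq_along(kw), keyword = kw, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_flagged") <- sum(flagged)
  out
}

#' @export
print.keyword_study <- function(x, ...) {
  cat(sprintf("<keyword_study> %d posts, %d comparison(s)\n",
              x$n_posts, length(x$results)))
  cat("corpus summary:\n")
  print(x$summary, row.names = FALSE)
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    if (inherits(r, "comparison_failure")) {
      cat(sprintf("  %-28s FAILED (%s)\n", nm, r$reason))
    } else {
      cat(sprintf("  %-28s %d tested, %d significant, %d retained\n", nm,
                  nrow(r$table), sum(r$table$significant),
                  length(r$keywords)))
    }
  }
  invisible(x)
}

#' @export
summary.keyword_study <- function(object, n = 10L, ...) {
  print(object)
  for (nm in names(object$results)) {
    r <- object$results[[nm]]
    if (inherits(r, "comparison_failure")) next
    kw <- utils::head(r$keywords, n)
    if (length(kw)) cat(sprintf("\n%s top keywords: %s\n", nm,
                                paste(kw, collapse = ", ")))
  }
  invisible(object)
}

#' Write all study outputs to a directory
#'
#' One TSV + JSON sidecar per comparison (via [write_comparison()]), the
#' corpus assignment as JSON, and a Markdown summary report. Output is
#' byte-identical across runs with the same inputs and seed.
#'
#' @param study A `keyword_study`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$results)) {
    r <- study$results[[nm]]
    if (inherits(r, "comparison_failure")) next
    write_comparison(r, file.path(outdir, paste0(nm, ".tsv")))
  }
  write_assignment(study$assignment, file.path(outdir, "assignment.json"))
  md <- c("# Keyword study report", "",
          sprintf("Posts: %d. Control partition seed: %d.",
                  study$n_posts, study$plan$seed),
          "", "## Corpus summary", "",
          "| drug | posts | % of total |", "| --- | ---: | ---: |",
          sprintf("| %s | %d | %s |", study$summary$drug,
                  study$summary$count, format(study$summary$percent)),
          "", "## Comparisons", "")
  for (nm in names(study$results)) {
    r <- study$results[[nm]]
    if (inherits(r, "comparison_failure")) {
      md <- c(md, sprintf("- **%s**: failed (%s)", nm, r$reason))
    } else {
      hl <- highlight_report(r, study$plan$highlight_terms)
      md <- c(md, sprintf(
        "- **%s**: %d words tested, %d significant, %d retained%s",
        nm, nrow(r$table), sum(r$table$significant), length(r$keywords),
        if (length(study$plan$highlight_terms))
          sprintf(", %d flagged by highlight list", attr(hl, "n_flagged"))
        else ""))
    }
  }
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}

#' Read / write a study plan as JSON
#'
#' Serializes the comparisons, control settings, seed and test
#' configuration (the lexicon travels separately; see [read_lexicon()]).
#'
#' @param path File path.
#' @return `read_plan()` returns a `study_plan`; `write_plan()` returns
#'   `path` invisibly.
#' @export
read_plan <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tc <- do.call(test_config, raw$test_config %||% list())
  study_plan(comparisons = raw$comparisons %||% default_comparisons(),
             control_k = raw$control_k %||% 4L,
             seed = raw$seed %||% 1L,
             test_config = tc,
             highlight_terms = unlist(raw$highlight_terms),
             pooling_map = unlist(raw$pooling_map),
             study_drugs = unlist(raw$study_drugs))
}

#' @rdname read_plan
#' @param plan A `study_plan`.
#' @export
write_plan <- function(plan, path) {
  out <- unclass(plan)
  out$test_config <- unclass(plan$test_config)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"), path)
  invisible(path)
}
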