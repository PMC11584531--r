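#' Read a collection of social-media posts
#'
#' Reads posts from JSON-lines (Pushshift Reddit submission schema: `id`,
#' `created_utc`, `title`, `selftext`) or CSV (`post_id`, `timestamp`,
#' `title`, `body`) and normalizes each record into the pipeline's internal
#' post representation: the title and body are joined with a single space
#' and lowercased into a `text` field. Usernames, comments and any other
#' fields are discarded; a missing title or body is treated as the empty
#' string. Records without a timestamp are skipped with a warning.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"`, `"csv"`, or `"auto"` (by file extension;
#'   `.jsonl`/`.json`/`.ndjson` read as JSON-lines, `.csv` as CSV).
#' @return A data frame of class `post_collection` with columns `post_id`,
#'   `timestamp` (seconds since epoch), `title`, `body`, `text`, one row per
#'   record in file order. The number of skipped records is available as
#'   `attr(x, "skipped")`.
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines('{"id":"a1","created_utc":100,"title":"Topamax question",
#'   "selftext":"Side effects?"}', f)
#' posts <- load_posts(f)
#' posts$text
#' @export
load_posts <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read posts file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    get_chr <- function(r, keys) {
      for (k in keys) {
        v <- r[[k]]
        if (!is.null(v) && length(v) == 1L && !is.na(v)) return(as.character(v))
      }
      ""
    }
    ids <- vapply(recs, get_chr, "", keys = c("id", "post_id"))
    ts <- vapply(recs, function(r) {
      v <- r[["created_utc"]] %||% r[["timestamp"]]
      if (is.null(v) || length(v) != 1L || is.na(suppressWarnings(as.numeric(v)))) NA_real_
      else as.numeric(v)
    }, 0)
    titles <- vapply(recs, get_chr, "", keys = "title")
    bodies <- vapply(recs, get_chr, "", keys = c("selftext", "body"))
  } else {
    df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
    need <- c("post_id", "timestamp", "title", "body")
    miss <- setdiff(c("post_id", "timestamp"), names(df))
    if (length(miss)) stop("CSV is missing required columns: ", paste(miss, collapse = ", "))
    for (k in setdiff(need, names(df))) df[[k]] <- ""
    ids <- df$post_id
    ts <- suppressWarnings(as.numeric(df$timestamp))
    ts[!nzchar(trimws(df$timestamp))] <- NA_real_
    titles <- df$title
    bodies <- df$body
    titles[is.na(titles)] <- ""
    bodies[is.na(bodies)] <- ""
  }
  keep <- !is.na(ts)
  n_skip <- sum(!keep)
  if (n_skip > 0L)
    warning(sprintf("skipped %d record(s) without a timestamp", n_skip))
  if (!length(ids) || all(!keep)) {
    out <- empty_posts()
    attr(out, "skipped") <- n_skip
    return(out)
  }
  ids <- ids[keep]
  blank <- !nzchar(ids)
  if (any(blank)) ids[blank] <- sprintf("post%06d", which(keep)[blank])
  if (anyDuplicated(ids)) stop("duplicate post_id in input: ", ids[duplicated(ids)][1L])
  out <- data.frame(
    post_id = ids,
    timestamp = ts[keep],
    title = titles[keep],
    body = bodies[keep],
    stringsAsFactors = FALSE
  )
  out$text <- normalize_post_text(out$title, out$body)
  class(out) <- c("post_collection", "data.frame")
  attr(out, "skipped") <- n_skip
  out
}

#' @noRd
empty_posts <- function() {
  out <- data.frame(post_id = character(), timestamp = numeric(),
                    title = character(), body = character(),
                    text = character(), stringsAsFactors = FALSE)
  class(out) <- c("post_collection", "data.frame")
  out
}

#' Normalize title and body into the analysis text
#'
#' Joins title and body with a single space (avoiding word-merging at the
#' boundary) and lowercases the result.
#' @param title,body Character vectors of equal length.
#' @return Lowercased character vector.
#' @export
normalize_post_text <- function(title, body) {
  title[is.na(title)] <- ""
  body[is.na(body)] <- ""
  tolower(trimws(paste(title, body)))
}

#' Restrict posts to a half-open date interval
#'
#' Keeps posts with `start <= timestamp < end`, preserving order. The
#' half-open convention means consecutive intervals partition a span
#' without double-counting boundary instants.
#'
#' @param posts A `post_collection` (or any data frame with a numeric
#'   `timestamp` column).
#' @param start,end Interval bounds in seconds since epoch (`start <= end`).
#' @return The filtered collection.
#' @export
filter_by_date <- function(posts, start = -Inf, end = Inf) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (start > end) stop("start must be <= end")
  posts[posts$timestamp >= start & posts$timestamp < end, , drop = FALSE]
}

#' Persist a post collection as JSON-lines
#'
#' Writes the Pushshift-style schema (`id`, `created_utc`, `title`,
#' `selftext`) that [load_posts()] reads, so a loaded collection round-trips.
#'
#' @param posts A `post_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posts_jsonl <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(list(id = posts$post_id[i],
                          created_utc = posts$timestamp[i],
                          title = posts$title[i],
                          selftext = posts$body[i]),
                     auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.post_collection <- function(x, ...) {
  cat(sprintf("<post_collection> %d post(s)", nrow(x)))
  if (nrow(x)) {
    rng <- range(x$timestamp)
    cat(sprintf(", timestamps [%s, %s]", format(rng[1]), format(rng[2])))
  }
  cat("\n")
  if (nrow(x)) {
    utils::str(utils::head(x$text, 3))
  }
  invisible(x)
}
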