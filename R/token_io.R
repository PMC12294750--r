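#' Construct a token table
#'
#' A token table holds one row per word token: the word, the context it
#' occurred in (the immediately preceding word in the utterance), and
#' optionally its duration in natural-log seconds. It is the input to every
#' other function in the package.
#'
#' @param word character vector of word symbols (non-empty strings).
#' @param context character vector of context symbols (the preceding word).
#' @param duration_log optional numeric vector of durations in natural-log
#'   seconds; must be finite where present.
#' @param token_id optional integer ids; defaults to `seq_along(word)`.
#'
#' @return A `data.frame` of class `token_table` with columns `token_id`,
#'   `word`, `context` and (if supplied) `duration_log`.
#' @export
#' @examples
#' token_table(word = c("dog", "cat"), context = c("the", "the"),
#'             duration_log = c(-1.2, -0.9))
token_table <- function(word, context, duration_log = NULL, token_id = NULL) {
  word <- as.character(word)
  context <- as.character(context)
  if (length(word) != length(context))
    stop("`word` and `context` must have the same length")
  if (is.null(token_id)) token_id <- seq_along(word)
  out <- data.frame(token_id = as.integer(token_id), word = word,
                    context = context, stringsAsFactors = FALSE)
  if (!is.null(duration_log)) out$duration_log <- as.numeric(duration_log)
  out <- validate_token_table(out)
  class(out) <- c("token_table", "data.frame")
  out
}

#' Validate a token table
#'
#' Checks the invariants of a token table: non-empty word and context symbols,
#' unique token ids, finite log durations. Called internally by every consumer.
#'
#' @param tokens a `data.frame` with at least columns `word` and `context`.
#' @return The validated table (invisibly classed as `token_table`).
#' @export
validate_token_table <- function(tokens) {
  stopifnot(is.data.frame(tokens))
  need <- c("word", "context")
  miss <- setdiff(need, names(tokens))
  if (length(miss))
    stop("token table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tokens)) {
    if (anyNA(tokens$word) || any(!nzchar(tokens$word)))
      stop("token table contains empty or missing `word` symbols")
    if (anyNA(tokens$context) || any(!nzchar(tokens$context)))
      stop("token table contains empty or missing `context` symbols")
    if ("token_id" %in% names(tokens) && anyDuplicated(tokens$token_id))
      stop("`token_id` values must be unique")
    if ("duration_log" %in% names(tokens) &&
        any(!is.finite(tokens$duration_log)))
      stop("`duration_log` must be finite for every row")
  }
  if (!"token_id" %in% names(tokens)) tokens$token_id <- seq_len(nrow(tokens))
  if (!inherits(tokens, "token_table"))
    class(tokens) <- c("token_table", class(tokens))
  invisible(tokens)
}

#' Read a token table from a delimited text file
#'
#' Reads a TSV or CSV file (delimiter inferred from the extension: `.tsv`
#' tab, `.csv` comma) with a header row naming the word, context and
#' (optionally) duration columns. Durations given in seconds are converted to
#' natural-log seconds; durations already on the log scale are taken as-is.
#' Rows with a missing or empty word or context symbol are dropped with a
#' warning reporting the count (utterance-initial tokens have no preceding
#' word and are expected to be absent from the input).
#'
#' @param path path to the file.
#' @param duration_unit `"seconds"` or `"log"`: the unit of the duration
#'   column in the file. Internally durations are always natural-log seconds.
#' @param col_word,col_context,col_duration column names in the file's header;
#'   set `col_duration = NULL` when the file has no duration column.
#' @param sep field delimiter; by default inferred from the file extension.
#'
#' @return A `token_table`; the input unit is recorded in
#'   `attr(x, "duration_unit_in")`.
#' @export
read_token_table <- function(path,
                             duration_unit = c("seconds", "log"),
                             col_word = "word",
                             col_context = "context",
                             col_duration = "duration",
                             sep = NULL) {
  duration_unit <- match.arg(duration_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8", check.names = FALSE)
  need <- c(col_word, col_context)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("input file lacks required column(s): ", paste(miss, collapse = ", "))
  word <- as.character(raw[[col_word]])
  context <- as.character(raw[[col_context]])
  has_dur <- !is.null(col_duration) && col_duration %in% names(raw)
  dur <- if (has_dur) as.numeric(raw[[col_duration]]) else NULL

  keep <- !is.na(word) & nzchar(word) & !is.na(context) & nzchar(context)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    warning(sprintf("dropped %d row(s) with missing word or context", n_drop))
    word <- word[keep]; context <- context[keep]
    if (has_dur) dur <- dur[keep]
  }
  if (has_dur) {
    if (duration_unit == "seconds") {
      bad <- which(!is.na(dur) & dur <= 0)
      if (length(bad))
        stop("non-positive duration in seconds at input row ", bad[1])
      dur <- log(dur)
    }
    if (anyNA(dur)) stop("missing duration values in input")
  }
  out <- token_table(word = word, context = context, duration_log = dur)
  attr(out, "duration_unit_in") <- duration_unit
  out
}

#' Write a token table to a delimited text file
#'
#' Inverse of [read_token_table()]: writes the `word`, `context` and (when
#' present) `duration_log` columns, with durations in natural-log seconds.
#' Reading the file back with `duration_unit = "log"` reproduces the table.
#'
#' @param tokens a `token_table`.
#' @param path output path; delimiter inferred from the extension as in
#'   [read_token_table()].
#' @return `path`, invisibly.
#' @export
write_token_table <- function(tokens, path) {
  tokens <- validate_token_table(tokens)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cols <- intersect(c("word", "context", "duration_log"), names(tokens))
  df <- as.data.frame(tokens)[, cols, drop = FALSE]
  if ("duration_log" %in% cols) names(df)[cols == "duration_log"] <- "duration"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive a per-replicate seed from a master seed
#'
#' Deterministically maps a `(master_seed, index)` pair to a seed in
#' `[0, 2^31 - 2]`. For a fixed master seed the map is injective in the
#' replicate index (an affine bijection modulo the prime 2^31 - 1), so
#' replicate streams never collide within an experiment and any run is
#' reproducible from the master seed alone.
#'
#' @param master_seed integer master seed.
#' @param index non-negative integer replicate index.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, 1)
derive_seed <- function(master_seed, index) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed),
            length(index) == 1, is.finite(index), index >= 0)
  m <- 2147483647 # 2^31 - 1, prime; products below stay exact in doubles
  h <- abs(as.double(master_seed)) %% m
  h <- (h * 69069 + 12345) %% m
  h <- (h + as.double(index)) %% m
  h <- (h * 69069 + 12345) %% m
  as.integer(h)
}
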