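#' Prescription corpora of standardized acupoint codes
#'
#' An `acu_corpus` holds one transaction per trial arm: a trial identifier and
#' the deduplicated set of standardized acupoint codes used in that arm.
#' Bilateral or repeated mentions of the same point collapse to a single code,
#' so per-point counts mean "number of prescriptions using the point".
#'
#' @param prescriptions named list of character vectors; names are trial ids,
#'   elements are acupoint codes (deduplicated and uppercased on construction).
#' @param vocabulary optional declared vocabulary. Defaults to the union of all
#'   prescription sets; a declared vocabulary that disagrees with the union is
#'   kept and reported by [validate_corpus()].
#' @return An object of class `acu_corpus` with elements `trial_id` (character),
#'   `items` (list of character vectors) and `vocabulary` (character).
#' @seealso [read_corpus()], [validate_corpus()], [generate_corpus()]
#' @export
#' @examples
#' acu_corpus(list(t1 = c("ST36", "CV12"), t2 = "ST36"))
acu_corpus <- function(prescriptions, vocabulary = NULL) {
  if (!is.list(prescriptions) || length(prescriptions) == 0L)
    stop("'prescriptions' must be a non-empty named list of character vectors")
  ids <- names(prescriptions)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every prescription needs a non-empty trial id (list names)")
  items <- lapply(prescriptions, function(x) sort(unique(toupper(as.character(x)))))
  if (any(lengths(items) == 0L))
    stop("empty prescription (no acupoints) for trial id(s): ",
         paste(ids[lengths(items) == 0L], collapse = ", "))
  union_vocab <- sort(unique(unlist(items, use.names = FALSE)))
  structure(
    list(trial_id = ids,
         items = unname(items),
         vocabulary = if (is.null(vocabulary)) union_vocab else sort(unique(toupper(vocabulary)))),
    class = "acu_corpus")
}

#' @export
print.acu_corpus <- function(x, ...) {
  cat(sprintf("<acu_corpus> %d prescriptions, %d acupoints, %d total usages\n",
              n_transactions(x), length(x$vocabulary), sum(lengths(x$items))))
  invisible(x)
}

#' Number of prescriptions (transactions) in a corpus
#' @param corpus an [acu_corpus()]
#' @return integer count
#' @export
n_transactions <- function(corpus) {
  stopifnot(inherits(corpus, "acu_corpus"))
  length(corpus$trial_id)
}

#' Corpus vocabulary
#' @param corpus an [acu_corpus()]
#' @return sorted character vector of acupoint codes
#' @export
corpus_vocabulary <- function(corpus) {
  stopifnot(inherits(corpus, "acu_corpus"))
  corpus$vocabulary
}

# Standard code syntax: meridian prefix + number (ST36, CV12, GV20) or the
# extra-point form EX-HN5.
code_pattern <- "^([A-Z]{2,3}[0-9]{1,3}|EX-[A-Z]{2}[0-9]{1,2})$"

is_valid_code <- function(x) grepl(code_pattern, x)

normalize_raw_name <- function(x) gsub("[ _]", "", tolower(trimws(x)))

#' Read an acupoint name map
#'
#' A name map translates raw point names as they appear in trial reports
#' (pinyin, spacing/case variants) to standardized codes. The CSV has two
#' columns, `raw_name` and `code`. Lookup is case- and space-insensitive.
#'
#' @param path CSV file with columns `raw_name,code`
#' @return named character vector: normalized raw name -> code
#' @export
read_name_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("raw_name", "code") %in% names(df)))
    stop("name map CSV must have columns 'raw_name' and 'code'")
  codes <- toupper(df$code)
  bad <- !is_valid_code(codes)
  if (any(bad))
    stop("invalid acupoint code(s) in name map: ", paste(unique(codes[bad]), collapse = ", "))
  stats::setNames(codes, normalize_raw_name(df$raw_name))
}

#' Built-in name map for the 42-point functional-dyspepsia vocabulary
#'
#' Pinyin aliases (e.g. "Zusanli" -> ST36, "Zhongwan" -> CV12) for the points
#' occurring in the shipped frequency fixture. Extensible by concatenating a
#' user map from [read_name_map()].
#' @return named character vector: normalized raw name -> code
#' @export
default_name_map <- function() {
  read_name_map(system.file("extdata", "name_map.csv", package = "acumine", mustWork = TRUE))
}

#' Standardize a raw acupoint name to its code
#'
#' Strings already in standard code syntax are uppercased and returned as-is
#' (the standard vocabulary is larger than any shipped alias map), so the
#' operation is idempotent. Anything else must resolve through `map`.
#'
#' @param raw character vector of raw names
#' @param map named character vector from [read_name_map()] / [default_name_map()]
#' @return character vector of standardized codes
#' @export
#' @examples
#' standardize_name(c("Zusanli", "ST36"), default_name_map())
standardize_name <- function(raw, map = default_name_map()) {
  if (length(map) == 0L) stop("name map is empty")
  raw <- as.character(raw)
  up <- toupper(trimws(raw))
  out <- ifelse(is_valid_code(up), up, unname(map[normalize_raw_name(raw)]))
  if (anyNA(out))
    stop("unknown acupoint name(s): ", paste(unique(raw[is.na(out)]), collapse = ", "))
  out
}

#' Read a prescription corpus from CSV or JSON
#'
#' CSV dialect: one row per prescription, first column the trial id, remaining
#' columns acupoint codes; a header row starting with `trial_id` is optional.
#' JSON: an array of objects `{"trial_id": ..., "acupoints": [...]}`.
#' Within-prescription duplicates are dropped with a warning; a prescription
#' left with zero acupoints is an error.
#'
#' @param path input file
#' @param format `"csv"` or `"json"`; default guessed from the file extension
#' @return an [acu_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(recs) == 0L) stop("empty corpus file: ", path)
    ids <- vapply(recs, function(r) as.character(r$trial_id), "")
    raw <- lapply(recs, function(r) toupper(unlist(r$acupoints)))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty corpus file: ", path)
    cells <- lapply(strsplit(lines, ","), function(x) trimws(x))
    if (tolower(cells[[1]][1]) == "trial_id") cells <- cells[-1]
    if (length(cells) == 0L) stop("corpus file has a header but no rows: ", path)
    ids <- vapply(cells, `[`, "", 1L)
    raw <- lapply(cells, function(x) toupper(x[-1][nzchar(x[-1])]))
  }
  ndup <- sum(vapply(raw, function(x) length(x) - length(unique(x)), 0L))
  if (ndup > 0L)
    warning(sprintf("dropped %d duplicate acupoint mention(s) within prescriptions", ndup))
  empty <- lengths(lapply(raw, unique)) == 0L
  if (any(empty))
    stop("prescription with zero acupoints after cleaning: ",
         paste(ids[empty], collapse = ", "))
  acu_corpus(stats::setNames(raw, ids))
}

#' Write a prescription corpus to CSV or JSON
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c, f))` reproduces the
#' corpus (prescription sets are written sorted).
#'
#' @param corpus an [acu_corpus()]
#' @param path output file
#' @param format `"csv"` or `"json"`; default guessed from the extension
#' @return `path`, invisibly
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(corpus, "acu_corpus"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    recs <- Map(function(id, it) list(trial_id = id, acupoints = it),
                corpus$trial_id, corpus$items)
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE)
  } else {
    writeLines(vapply(seq_along(corpus$trial_id), function(i)
      paste(c(corpus$trial_id[i], corpus$items[[i]]), collapse = ","), ""), path)
  }
  invisible(path)
}

#' Check corpus invariants
#'
#' Reports (never throws) violations of the corpus contract: syntactically
#' invalid or non-uppercase codes, duplicate codes within a prescription,
#' empty prescriptions, duplicate trial ids, and disagreement between the
#' declared vocabulary and the union of prescription sets.
#'
#' @param corpus an [acu_corpus()] (or a structurally similar list, so that
#'   invalid states produced outside the constructor can be audited)
#' @return data.frame with columns `trial_id` and `reason`; zero rows iff all
#'   invariants hold
#' @export
validate_corpus <- function(corpus) {
  viol <- list()
  add <- function(id, reason) viol[[length(viol) + 1L]] <<- data.frame(
    trial_id = id, reason = reason, stringsAsFactors = FALSE)
  ids <- corpus$trial_id
  if (anyDuplicated(ids))
    for (id in unique(ids[duplicated(ids)])) add(id, "duplicate trial id")
  for (i in seq_along(ids)) {
    x <- corpus$items[[i]]
    if (length(x) == 0L) add(ids[i], "empty prescription")
    if (anyDuplicated(x)) add(ids[i], "duplicate acupoint codes in prescription")
    bad <- x[!is_valid_code(x)]
    for (b in bad) add(ids[i], paste0("invalid acupoint code: ", b))
  }
  used <- sort(unique(unlist(corpus$items, use.names = FALSE)))
  unused <- setdiff(corpus$vocabulary, used)
  for (u in unused) add("<vocabulary>", paste0("vocabulary code used in no prescription: ", u))
  missing <- setdiff(used, corpus$vocabulary)
  for (m in missing) add("<vocabulary>", paste0("used code absent from vocabulary: ", m))
  if (length(viol) == 0L)
    return(data.frame(trial_id = character(), reason = character(), stringsAsFactors = FALSE))
  do.call(rbind, viol)
}
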