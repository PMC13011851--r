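#' Round half away from zero
#'
#' Reporting convention used throughout: printed percentages and lifts round
#' half away from zero (so 1.015 -> 1.02), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# n x V logical incidence matrix: inc[t, j] <=> prescription t uses item j.
incidence_matrix <- function(corpus) {
  vocab <- corpus_vocabulary(corpus)
  inc <- matrix(FALSE, n_transactions(corpus), length(vocab),
                dimnames = list(corpus$trial_id, vocab))
  for (i in seq_along(corpus$items))
    inc[i, match(corpus$items[[i]], vocab)] <- TRUE
  inc
}

#' Acupoint usage frequency table
#'
#' Counts, for every vocabulary item, the number of prescriptions using it.
#' The percent column supports the two denominator conventions found in
#' prescription-mining reports: share of all point usages
#' (`"total_usages"`, the printed frequency-table style) or transaction
#' support (`"n_transactions"`, count / number of prescriptions).
#'
#' @param corpus an [acu_corpus()]
#' @param mode denominator convention, `"total_usages"` or `"n_transactions"`
#' @return data.frame with columns `code`, `count`, `percent` (raw, unrounded),
#'   ordered by count descending then code; attributes `denominator_mode` and
#'   `denominator`
#' @export
frequency_table <- function(corpus, mode = c("total_usages", "n_transactions")) {
  mode <- match.arg(mode)
  inc <- incidence_matrix(corpus)
  count <- colSums(inc)
  denom <- if (mode == "total_usages") sum(count) else nrow(inc)
  df <- data.frame(code = colnames(inc), count = as.integer(count),
                   percent = 100 * count / denom,
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$count, df$code), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "denominator_mode") <- mode
  attr(df, "denominator") <- denom
  df
}

#' Co-occurrence (co-prescription) count matrix
#'
#' Symmetric matrix whose off-diagonal entry (i, j) is the number of
#' prescriptions containing both points, and whose diagonal is the per-point
#' prescription count. Items are ordered by frequency (count descending, then
#' code), the heat-map-ready ordering.
#'
#' @param corpus an [acu_corpus()]
#' @return integer matrix with dimnames = item codes
#' @export
cooccurrence_matrix <- function(corpus) {
  inc <- incidence_matrix(corpus)
  ord <- order(-colSums(inc), colnames(inc))
  m <- crossprod(inc[, ord, drop = FALSE] * 1L)
  storage.mode(m) <- "integer"
  m
}

#' Write a co-occurrence matrix as TSV
#' @param m matrix from [cooccurrence_matrix()]
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_cooccurrence <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Frequent itemsets by level-wise Apriori search
#'
#' Classic Apriori: candidates of size k are joins of frequent (k-1)-sets
#' sharing a (k-2)-prefix, pruned by downward closure, then support-counted
#' against the corpus. Emits exactly the itemsets of size <= `max_size` with
#' transaction support >= `min_support`.
#'
#' @param corpus an [acu_corpus()]
#' @param min_support minimum transaction support in (0, 1]
#' @param max_size largest itemset size searched
#' @return data.frame with list-column `items`, plus `size`, `support_count`
#'   and `support`; ordered by size, support descending, then items
#' @export
frequent_itemsets <- function(corpus, min_support, max_size = 3L) {
  stopifnot(min_support > 0, min_support <= 1, max_size >= 1L)
  inc <- incidence_matrix(corpus)
  n <- nrow(inc)
  vocab <- colnames(inc)
  eps <- 1e-12
  min_count <- min_support * n - eps

  counts1 <- colSums(inc)
  keep <- unname(which(counts1 >= min_count))
  level <- lapply(keep, function(j) j)           # itemsets as sorted index vectors
  level_counts <- counts1[keep]
  all_sets <- level; all_counts <- as.numeric(level_counts)

  k <- 1L
  while (k < max_size && length(level) > 1L) {
    prefix <- vapply(level, function(s) paste(s[-length(s)], collapse = "."), "")
    cand <- list()
    for (p in unique(prefix)) {
      grp <- level[prefix == p]
      if (length(grp) < 2L) next
      last <- vapply(grp, function(s) s[length(s)], 0L)
      o <- order(last)
      grp <- grp[o]; last <- last[o]
      for (a in seq_len(length(grp) - 1L))
        for (b in seq((a + 1L), length(grp)))
          cand[[length(cand) + 1L]] <- c(grp[[a]], last[b])
    }
    if (length(cand) == 0L) break
    # downward-closure pruning
    freq_keys <- vapply(level, paste, "", collapse = ".")
    ok <- vapply(cand, function(s) {
      subs <- vapply(seq_along(s), function(i) paste(s[-i], collapse = "."), "")
      all(subs %in% freq_keys)
    }, TRUE)
    cand <- cand[ok]
    if (length(cand) == 0L) break
    cnt <- vapply(cand, function(s) sum(rowSums(inc[, s, drop = FALSE]) == length(s)), 0)
    sel <- cnt >= min_count
    level <- cand[sel]; level_counts <- cnt[sel]
    all_sets <- c(all_sets, level); all_counts <- c(all_counts, level_counts)
    k <- k + 1L
  }

  items <- lapply(all_sets, function(s) vocab[s])
  df <- data.frame(size = lengths(items),
                   support_count = as.integer(round(all_counts)),
                   support = all_counts / n)
  df$items <- items
  key <- vapply(items, paste, "", collapse = "+")
  df <- df[order(df$size, -df$support, key), c("items", "size", "support_count", "support")]
  rownames(df) <- NULL
  df
}

#' Mine association rules between acupoints
#'
#' Rules have a single-item consequent. Following the convention of the
#' printed rule tables in acupoint-prescription mining (verifiable by
#' back-solving their support columns), the reported "support" of a rule is
#' the ANTECEDENT's joint transaction support, not the joint support of
#' antecedent plus consequent; a rule is emitted iff
#' `support(antecedent) >= min_support` and `confidence >= min_confidence`.
#' Expected confidence is the consequent's unconditional transaction support
#' and lift = confidence / expected confidence.
#'
#' @param corpus an [acu_corpus()]
#' @param min_support minimum antecedent support, fraction in (0, 1]
#' @param min_confidence minimum confidence, fraction in (0, 1]
#' @param max_antecedent largest antecedent size
#' @return data.frame with columns `antecedent` (codes joined by `+`),
#'   `consequent`, `support`, `confidence`, `expected_confidence` (percent,
#'   unrounded), `lift`, plus list-column `antecedent_items`; ordered by
#'   support descending (ties: antecedent, consequent). Use
#'   [format_rules()] for the printed 2-dp layout.
#' @export
association_rules <- function(corpus, min_support = 0.20, min_confidence = 0.80,
                              max_antecedent = 2L) {
  stopifnot(min_confidence > 0, min_confidence <= 1, max_antecedent >= 1L)
  inc <- incidence_matrix(corpus)
  n <- nrow(inc)
  item_count <- colSums(inc)
  ante <- frequent_itemsets(corpus, min_support, max_size = max_antecedent)
  eps <- 1e-12
  rows <- list()
  for (i in seq_len(nrow(ante))) {
    a_items <- ante$items[[i]]
    in_a <- rowSums(inc[, a_items, drop = FALSE]) == length(a_items)
    n_a <- ante$support_count[i]
    joint <- colSums(inc[in_a, , drop = FALSE])
    for (cons in setdiff(colnames(inc), a_items)) {
      conf <- joint[[cons]] / n_a
      if (conf + eps < min_confidence) next
      exp_conf <- item_count[[cons]] / n
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = paste(a_items, collapse = "+"),
        consequent = cons,
        support = 100 * n_a / n,
        confidence = 100 * conf,
        expected_confidence = 100 * exp_conf,
        lift = conf / exp_conf,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$antecedent_items <- list(a_items)
    }
  }
  if (length(rows) == 0L) {
    df <- data.frame(antecedent = character(), consequent = character(),
                     support = numeric(), confidence = numeric(),
                     expected_confidence = numeric(), lift = numeric(),
                     stringsAsFactors = FALSE)
    df$antecedent_items <- list()
    return(df)
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$support, df$antecedent, df$consequent), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Format a rule table at printed precision
#'
#' Rounds percentages and lift to 2 decimals, half away from zero, matching
#' the printed rule-table layout.
#' @param rules data.frame from [association_rules()]
#' @return data.frame without the list column, numerics rounded to 2 dp
#' @export
format_rules <- function(rules) {
  out <- rules[setdiff(names(rules), "antecedent_items")]
  for (col in c("support", "confidence", "expected_confidence", "lift"))
    out[[col]] <- round_half_up(out[[col]], 2)
  out
}

#' Lift (enhancement coefficient) of a rule
#'
#' The interdependence measure of a rule: confidence divided by expected
#' confidence (the consequent's unconditional support). Values above 1
#' indicate positive co-selection dependence between antecedent and
#' consequent. Both arguments may be on the percent or the fraction scale, as
#' long as they agree.
#'
#' @param confidence rule confidence
#' @param expected_confidence consequent support
#' @param digits if non-NULL, round the ratio half-away-from-zero to this many
#'   decimals (the reporting convention is 2)
#' @return numeric lift ratio
#' @export
#' @examples
#' rule_lift(90.63, 89.13, digits = 2)   # 1.02
#' rule_lift(100.00, 69.57, digits = 2)  # 1.44
rule_lift <- function(confidence, expected_confidence, digits = NULL) {
  if (any(expected_confidence <= 0))
    stop("expected confidence must be positive")
  out <- confidence / expected_confidence
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}
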