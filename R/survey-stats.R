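#' Content validity ratio (Lawshe)
#'
#' `CVR = (n_e - N/2) / (N/2)` where `n_e` is the number of experts rating an
#' item essential and `N` the panel size. Ranges from -1 (nobody) through 0
#' (exactly half) to 1 (unanimous).
#'
#' @param n_e Number of "essential" ratings (0..N). Vectorised.
#' @param N Total number of experts (>= 1).
#' @return Numeric CVR value(s) in `[-1, 1]`.
#' @examples
#' cvr(7, 10)  # 0.4
#' @export
cvr <- function(n_e, N) {
  if (length(N) != 1L || is.na(N) || N < 1 || N != round(N)) {
    stop("N must be a positive integer")
  }
  if (anyNA(n_e) || any(n_e < 0) || any(n_e > N) || any(n_e != round(n_e))) {
    stop("n_e must be integers in 0..N")
  }
  (n_e - N / 2) / (N / 2)
}

#' Lawshe critical values
#'
#' Reads the critical-value table shipped as editable configuration
#' (`inst/extdata/lawshe-critical-values.csv`; columns `n_experts`,
#' `critical_value`) and returns the value for a panel size. The shipped
#' defaults are the widely reproduced one-tailed p = .05 values; replace the
#' CSV (or pass `table`) for other conventions.
#'
#' @param N Panel size.
#' @param table Optional data frame overriding the shipped CSV.
#' @return The critical CVR value for `N`.
#' @export
lawshe_critical <- function(N, table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "lawshe-critical-values.csv",
                        package = "ltxcdss")
    table <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("n_experts", "critical_value") %in% names(table)))
  i <- match(N, table$n_experts)
  if (is.na(i)) {
    stop("no critical value tabulated for N = ", N,
         " (tabulated: ", paste(table$n_experts, collapse = ", "), ")")
  }
  table$critical_value[i]
}

#' Partition survey items into retained and discarded
#'
#' An item is retained iff its CVR meets the critical value and (when mean
#' scores are supplied) its mean meets `mean_keep`. Items whose mean falls in
#' the gap `[mean_drop, mean_keep)` are flagged `borderline` rather than
#' silently classified — the retention thresholds are caller-supplied
#' parameters, not constants.
#'
#' @param cvr_values Numeric vector of per-item CVRs.
#' @param critical_value CVR retention threshold (see [lawshe_critical()]).
#' @param mean_scores Optional per-item mean ratings.
#' @param mean_keep Mean-score retention threshold (retain at or above).
#' @param mean_drop Mean-score discard threshold (discard strictly below).
#' @param items Optional item labels.
#' @return Data frame with columns `item`, `cvr`, `mean_score`, `decision`
#'   (`retained` / `discarded` / `borderline`).
#' @export
retain_items <- function(cvr_values, critical_value, mean_scores = NULL,
                         mean_keep = 3.6, mean_drop = 3.5, items = NULL) {
  k <- length(cvr_values)
  if (is.null(items)) items <- paste0("item_", seq_len(k))
  stopifnot(length(items) == k, mean_drop <= mean_keep)
  cvr_ok <- cvr_values >= critical_value
  if (is.null(mean_scores)) {
    decision <- ifelse(cvr_ok, "retained", "discarded")
    mean_scores <- rep(NA_real_, k)
  } else {
    stopifnot(length(mean_scores) == k)
    decision <- ifelse(!cvr_ok | mean_scores < mean_drop, "discarded",
                ifelse(mean_scores >= mean_keep, "retained", "borderline"))
  }
  data.frame(item = items, cvr = cvr_values, mean_score = mean_scores,
             decision = decision, stringsAsFactors = FALSE)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a respondents x items score matrix:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`,
#' with sample variances.
#'
#' @param matrix Numeric matrix or data frame, respondents in rows, items in
#'   columns; at least 2 of each, no missing cells (rows with missing cells
#'   are dropped listwise with a warning).
#' @return The alpha coefficient.
#' @examples
#' cronbach_alpha(cbind(c(1, 2, 3), c(2, 4, 6)))  # 0.889
#' @export
cronbach_alpha <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("score matrix must be numeric")
  if (anyNA(m)) {
    keep <- stats::complete.cases(m)
    warning("dropped ", sum(!keep), " respondent(s) with missing cells (listwise)")
    m <- m[keep, , drop = FALSE]
  }
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 items")
  if (nrow(m) < 2L) stop("need at least 2 respondents")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop("degenerate input: total-score variance is zero")
  }
  item_var <- apply(m, 2, stats::var)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Default PSSUQ item-to-subscale map
#'
#' The 16-item Version-3 layout: items 1-6 system usefulness, 7-12
#' information quality, 13-15 interface quality, 1-16 overall. Fully
#' user-overridable — pass any named map to [pssuq_scores()].
#'
#' @return Named character vector: `item_1` ... `item_16` -> subscale.
#' @export
pssuq_default_map <- function() {
  stats::setNames(
    c(rep("system_usefulness", 6), rep("information_quality", 6),
      rep("interface_quality", 3), "overall_only"),
    paste0("item_", 1:16))
}

.pssuq_subscales <- c("system_usefulness", "information_quality",
                      "interface_quality")

#' PSSUQ subscale scoring
#'
#' A respondent's subscale score is the mean of their ratings on the items
#' mapped to that subscale; the overall score is the mean over all items.
#' Pooled statistics (mean, median, sample SD) are taken across respondents.
#' With a single respondent the SD is reported as `NA`.
#'
#' @param matrix Respondents x items numeric matrix or data frame; column
#'   names must appear in `item_map`.
#' @param item_map Named character vector mapping every item (column) to a
#'   subscale; see [pssuq_default_map()].
#' @return An `ltx_pssuq`: `respondent` (per-respondent subscale scores) and
#'   `pooled` (data frame: `subscale`, `mean`, `median`, `sd`, `n`).
#' @export
pssuq_scores <- function(matrix, item_map = pssuq_default_map()) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("score matrix must be numeric")
  items <- colnames(m)
  if (is.null(items)) {
    items <- names(item_map)[seq_len(ncol(m))]
    colnames(m) <- items
  }
  unmapped <- setdiff(items, names(item_map))
  if (length(unmapped)) {
    stop("unmapped item(s): ", paste(unmapped, collapse = ", "))
  }
  sub_of <- item_map[items]
  per_resp <- data.frame(row.names = seq_len(nrow(m)))
  for (s in .pssuq_subscales) {
    cols <- items[sub_of == s]
    if (length(cols)) per_resp[[s]] <- rowMeans(m[, cols, drop = FALSE])
  }
  per_resp$overall <- rowMeans(m)
  structure(list(respondent = per_resp,
                 pooled = pssuq_pooled(per_resp)),
            class = "ltx_pssuq")
}

#' Pool subscale-level PSSUQ scores across respondents
#'
#' For reproducing published subscale tables whose inputs are already
#' per-respondent subscale scores (item-level responses unavailable).
#'
#' @param scores Data frame or matrix, respondents in rows, one column per
#'   subscale.
#' @return Data frame: `subscale`, `mean`, `median`, `sd` (sample SD; `NA`
#'   with one respondent), `n`.
#' @export
pssuq_pooled <- function(scores) {
  s <- as.data.frame(scores)
  out <- do.call(rbind, lapply(names(s), function(nm) {
    v <- s[[nm]]
    data.frame(subscale = nm, mean = mean(v), median = stats::median(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ltx_pssuq <- function(x, ...) {
  cat("<PSSUQ scores> ", nrow(x$respondent), " respondent(s)\n", sep = "")
  p <- x$pooled
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-20s mean %.4f  median %.2f  sd %s\n", p$subscale[i],
                p$mean[i], p$median[i],
                if (is.na(p$sd[i])) "NA" else sprintf("%.3f", p$sd[i])))
  }
  invisible(x)
}
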