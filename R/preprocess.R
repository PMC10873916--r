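#' Respondent-by-item ordinal response table
#'
#' The raw-input container of the pipeline: an integer matrix of survey
#' responses with per-item metadata (scale membership and admissible range)
#' and an optional binary group label per respondent.
#'
#' @param values respondent x item matrix (integers or missing), with column
#'   names identifying the items.
#' @param item_meta data.frame with columns `item`, `scale` (one of `PHQ`,
#'   `GAD`, `IES`, `STRESSOR`, `SUPPORT`, `OTHER`), `min`, `max`. Defaults to
#'   `OTHER` items spanning the observed range.
#' @param group optional per-respondent binary label (0/1).
#' @return an object of class `item_response_table`.
#' @export
item_response_table <- function(values, item_meta = NULL, group = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("item", seq_len(ncol(values)))
  if (is.null(item_meta)) {
    item_meta <- data.frame(
      item = colnames(values), scale = "OTHER",
      min = apply(values, 2, min, na.rm = TRUE),
      max = apply(values, 2, max, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("item", "scale", "min", "max") %in% names(item_meta)),
            setequal(item_meta$item, colnames(values)))
  item_meta <- item_meta[match(colnames(values), item_meta$item), ]
  rownames(item_meta) <- NULL
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    ok <- is.na(v) | (v >= item_meta$min[j] & v <= item_meta$max[j])
    if (!all(ok))
      stop("item ", colnames(values)[j], " has values outside [",
           item_meta$min[j], ", ", item_meta$max[j], "]")
  }
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(values), all(group %in% c(0, 1)))
    group <- as.integer(group)
  }
  structure(list(values = values, item_meta = item_meta, group = group),
            class = "item_response_table")
}

#' @export
print.item_response_table <- function(x, ...) {
  cat("Item response table:", nrow(x$values), "respondents x",
      ncol(x$values), "items\n")
  cat("scales:", paste(unique(x$item_meta$scale), collapse = ", "), "\n")
  if (!is.null(x$group))
    cat("group labels: 0 (n=", sum(x$group == 0), "), 1 (n=",
        sum(x$group == 1), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.item_response_table <- function(x, ...) {
  df <- as.data.frame(x$values)
  if (!is.null(x$group)) df$group <- x$group
  df
}

#' Write / read an item response table as CSV
#'
#' One respondent per row; the header carries item labels and, when present,
#' a final `group` column.
#'
#' @param table an [item_response_table()].
#' @param path CSV file path.
#' @export
write_response_csv <- function(table, path) {
  stopifnot(inherits(table, "item_response_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_csv
#' @param item_meta optional metadata passed to [item_response_table()].
#' @export
read_response_csv <- function(path, item_meta = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  group <- NULL
  if ("group" %in% names(df)) {
    group <- df$group
    df$group <- NULL
  }
  item_response_table(as.matrix(df), item_meta = item_meta, group = group)
}

#' Drop respondents with missing core items
#'
#' Retains only respondents with no missing value on any of the core items,
#' mirroring the usual survey exclusion rule for core measures. The number of
#' removed rows is recorded in attribute `n_removed`.
#'
#' @param table an [item_response_table()].
#' @param core_items item names that must be complete; defaults to all items.
#' @export
filter_complete_cases <- function(table, core_items = NULL) {
  stopifnot(inherits(table, "item_response_table"))
  if (is.null(core_items)) core_items <- colnames(table$values)
  missing_items <- setdiff(core_items, colnames(table$values))
  if (length(missing_items))
    stop("unknown core items: ", paste(missing_items, collapse = ", "))
  keep <- stats::complete.cases(table$values[, core_items, drop = FALSE])
  if (!any(keep)) stop("no complete cases remain")
  out <- item_response_table(table$values[keep, , drop = FALSE],
                             item_meta = table$item_meta,
                             group = if (!is.null(table$group)) table$group[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Total score on a symptom scale
#'
#' Sums the item values of one scale per respondent; higher totals indicate
#' more severe symptoms.
#'
#' @param table an [item_response_table()].
#' @param scale_id scale name as in `item_meta$scale` (e.g. `"PHQ"`).
#' @return numeric vector of per-respondent totals.
#' @export
score_scale <- function(table, scale_id) {
  stopifnot(inherits(table, "item_response_table"))
  items <- table$item_meta$item[table$item_meta$scale == scale_id]
  if (!length(items)) stop("no items belong to scale ", scale_id)
  vals <- table$values[, items, drop = FALSE]
  if (anyNA(vals))
    stop("scale ", scale_id, " has missing values; filter complete cases first")
  rowSums(vals)
}

#' Probable-case classification from a scale total
#'
#' A respondent is a probable case when the scale total reaches the
#' threshold (10 by default for PHQ-9 / GAD-7 / IES-6 caseness).
#'
#' @param total numeric vector of scale totals (>= 0).
#' @param threshold caseness cut-off; a total of exactly `threshold` counts
#'   as a case.
#' @export
classify_probable_case <- function(total, threshold = 10) {
  stopifnot(all(total >= 0))
  total >= threshold
}

#' Merge two correlated stressor domain ratings
#'
#' Highly correlated stressor domains are combined by taking the mean of the
#' two 0-4 ratings.
#'
#' @param a,b numeric ratings in `[0, 4]`.
#' @export
merge_stressor_domains <- function(a, b) {
  if (any(a < 0 | a > 4 | b < 0 | b > 4, na.rm = TRUE))
    stop("stressor ratings must lie in [0, 4]")
  (a + b) / 2
}

#' Collapse a stressor rating into three levels
#'
#' Ratings are collapsed to 0 (not stressful), 1 (a little stressful) and
#' 2 (stressful to extremely stressful, i.e. a rating of 2 or more).
#' Fractional merged ratings use the boundaries 0 -> 0, (0, 2) -> 1,
#' `[2, 4]` -> 2, which preserves the "2 or more is stressful" anchor.
#'
#' @param rating numeric rating(s) in `[0, 4]`.
#' @return integer level(s) in `{0, 1, 2}`.
#' @export
collapse_stressor_levels <- function(rating) {
  if (any(rating < 0, na.rm = TRUE)) stop("stressor ratings cannot be negative")
  if (any(rating > 4, na.rm = TRUE)) stop("stressor ratings must lie in [0, 4]")
  out <- ifelse(rating >= 2, 2L, ifelse(rating > 0, 1L, 0L))
  storage.mode(out) <- "integer"
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of total)`.
#'
#' @param items respondent x k matrix (k >= 2, no missing values).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  if (anyNA(items)) stop("missing values not allowed")
  vt <- var(rowSums(items))
  if (vt <= 0) stop("total score has zero variance")
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / vt)
}

#' Odds ratio with Wald confidence interval and chi-square test
#'
#' For a 2x2 table `matrix(c(a, b, c, d), 2)` (exposed cases `a`, exposed
#' non-cases `b`, unexposed cases `c`, unexposed non-cases `d` arranged
#' row-wise as exposure x outcome), computes `OR = ad/bc`, the 95% Wald
#' interval on the log scale and a continuity-corrected chi-square p-value.
#' A zero cell triggers the Haldane-Anscombe 0.5 correction (flagged).
#'
#' @param table2x2 2x2 matrix of non-negative counts.
#' @param conf_level confidence level for the Wald interval.
#' @param exact also report Fisher's exact p-value.
#' @return list with `or`, `ci`, `p`, `corrected` (Haldane flag) and
#'   optionally `p_exact`.
#' @export
odds_ratio <- function(table2x2, conf_level = 0.95, exact = FALSE) {
  x <- as.matrix(table2x2)
  stopifnot(all(dim(x) == c(2, 2)), all(x >= 0))
  corrected <- any(x == 0)
  xc <- if (corrected) x + 0.5 else x
  or <- (xc[1, 1] * xc[2, 2]) / (xc[1, 2] * xc[2, 1])
  se <- sqrt(sum(1 / xc))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- suppressWarnings(chisq.test(x, correct = TRUE)$p.value)
  out <- list(or = or, ci = ci, p = p, corrected = corrected)
  if (exact) out$p_exact <- stats::fisher.test(x)$p.value
  out
}

# default merge plan of the study layout: 7 stressor domains -> 4 nodes
default_merge_plan <- function() {
  list(FW = c("STR_finance", "STR_work"),
       PHY = "STR_physical",
       MF = c("STR_medical", "STR_food"),
       FFC = c("STR_family", "STR_friends"))
}

#' Build the analysis node matrix
#'
#' Passes symptom and support items through unchanged, merges paired stressor
#' domains by their mean rating and collapses every stressor node into three
#' levels. Stressor items not named in the merge plan are collapsed
#' individually. When the table follows the canonical study layout the nodes
#' are ordered PHQ1..9, GAD1..7, IES1..6, FW, PHY, MF, FFC, SSFm, SSFr.
#'
#' @param table an [item_response_table()] (complete cases).
#' @param merge_plan named list: node name -> character vector of one or two
#'   stressor item names. `NULL` collapses stressors individually.
#' @return a numeric respondent x node matrix of class `node_matrix` with
#'   attributes `node_groups` (scale membership) and `group` (respondent
#'   labels, when present).
#' @export
build_node_matrix <- function(table, merge_plan = NULL) {
  stopifnot(inherits(table, "item_response_table"))
  if (anyNA(table$values))
    stop("missing values present; filter complete cases first")
  meta <- table$item_meta
  planned <- unlist(merge_plan, use.names = FALSE)
  unknown <- setdiff(planned, meta$item)
  if (length(unknown))
    stop("merge plan references unknown items: ",
         paste(unknown, collapse = ", "))
  sym_items <- meta$item[meta$scale %in% c("PHQ", "GAD", "IES")]
  sup_items <- meta$item[meta$scale == "SUPPORT"]
  str_items <- meta$item[meta$scale == "STRESSOR"]
  other_items <- meta$item[meta$scale == "OTHER"]
  cols <- list()
  groups <- character(0)
  for (it in c(sym_items, other_items)) {
    cols[[it]] <- as.numeric(table$values[, it])
    groups <- c(groups, meta$scale[meta$item == it])
  }
  for (nd in names(merge_plan)) {
    its <- merge_plan[[nd]]
    if (!all(its %in% str_items))
      stop("merge plan node ", nd, " references non-stressor items")
    merged <- if (length(its) == 2) {
      merge_stressor_domains(table$values[, its[1]], table$values[, its[2]])
    } else as.numeric(table$values[, its])
    cols[[nd]] <- as.numeric(collapse_stressor_levels(merged))
    groups <- c(groups, "STRESSOR")
  }
  for (it in setdiff(str_items, planned)) {
    cols[[it]] <- as.numeric(collapse_stressor_levels(table$values[, it]))
    groups <- c(groups, "STRESSOR")
  }
  for (it in sup_items) {
    cols[[it]] <- as.numeric(table$values[, it])
    groups <- c(groups, "SUPPORT")
  }
  m <- do.call(cbind, cols)
  names(groups) <- colnames(m)
  canonical <- study_node_labels()
  if (setequal(colnames(m), canonical)) {
    m <- m[, canonical, drop = FALSE]
    groups <- groups[canonical]
  }
  structure(m, node_groups = groups,
            group = table$group, class = c("node_matrix", "matrix"))
}

#' @export
print.node_matrix <- function(x, ...) {
  cat("Node data matrix:", nrow(x), "respondents x", ncol(x), "nodes\n")
  tab <- table(attr(x, "node_groups"))
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Descriptive summary table for an item response table
#'
#' Per-scale totals, caseness proportions and, when a group label is present,
#' odds ratios of caseness by group — the descriptive layer that usually
#' accompanies a symptom-network analysis.
#'
#' @param table an [item_response_table()].
#' @param threshold caseness threshold applied to each symptom scale.
#' @return data.frame with one row per symptom scale.
#' @export
describe_sample <- function(table, threshold = 10) {
  stopifnot(inherits(table, "item_response_table"))
  scales <- intersect(c("PHQ", "GAD", "IES"), unique(table$item_meta$scale))
  rows <- lapply(scales, function(sc) {
    tot <- score_scale(table, sc)
    case <- classify_probable_case(tot, threshold)
    row <- data.frame(scale = sc, mean_total = mean(tot),
                      n_cases = sum(case), pct_cases = 100 * mean(case))
    if (!is.null(table$group)) {
      tab <- matrix(c(sum(case & table$group == 1), sum(!case & table$group == 1),
                      sum(case & table$group == 0), sum(!case & table$group == 0)),
                    2, byrow = TRUE)
      orr <- odds_ratio(tab)
      row$or_group <- orr$or
      row$or_p <- orr$p
    }
    row
  })
  do.call(rbind, rows)
}
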