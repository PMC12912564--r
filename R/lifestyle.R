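# Lifestyle-change scoring: frequency-sum scores for the typical and
# pandemic phases of an experiences questionnaire, and per-item paired tests
# of change with Bonferroni control.

#' Score typical and pandemic lifestyle from item-level responses
#'
#' Sums 0-5 frequency responses over non-excluded items per phase. The
#' default scoring is the unweighted frequency sum; a named `weights` vector
#' allows an instrument-specific weighting scheme to be dropped in. Subjects
#' missing any non-excluded item in either phase are flagged incomplete and
#' carry `NA` scores for the affected phase (and hence `NA` change), so they
#' drop out of change analyses rather than receiving a deflated sum.
#'
#' @param item_table Tibble/data frame with columns `subject_id`, `item_id`,
#'   `phase` (`"typical"`/`"pandemic"`), `response` (integer 0-5).
#' @param exclusions Character vector of `item_id`s to drop before scoring
#'   (e.g. items biased by the reporting time frame, such as travel counts).
#' @param weights Optional named numeric vector of per-item weights; items
#'   absent from the vector get weight 1.
#' @return Tibble with `subject_id`, `typical`, `pandemic`,
#'   `change` (= typical - pandemic), `complete`.
#' @export
score_leq <- function(item_table, exclusions = character(), weights = NULL) {
  item_table <- validate_items(item_table)
  keep <- !(item_table$item_id %in% exclusions)
  tab <- item_table[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("no items left after exclusions", call. = FALSE)
  items <- sort(unique(tab$item_id))
  w <- stats::setNames(rep(1, length(items)), items)
  if (!is.null(weights)) w[names(weights)[names(weights) %in% items]] <-
      weights[names(weights) %in% items]
  tab$w_resp <- tab$response * w[tab$item_id]

  phase_score <- function(ph) {
    sub <- tab[tab$phase == ph, ]
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$subject_id),
      score = sum(.data$w_resp),
      n_items = dplyr::n_distinct(.data$item_id),
      .groups = "drop"
    )
    agg$score[agg$n_items < length(items)] <- NA_real_
    agg[, c("subject_id", "score")]
  }
  typ <- phase_score("typical")
  pan <- phase_score("pandemic")
  out <- dplyr::full_join(
    dplyr::rename(typ, typical = "score"),
    dplyr::rename(pan, pandemic = "score"),
    by = "subject_id"
  )
  out$change <- out$typical - out$pandemic
  out$complete <- !is.na(out$change)
  dplyr::arrange(tibble::as_tibble(out), .data$subject_id)
}

#' Per-item tests of lifestyle change
#'
#' Paired Wilcoxon signed-rank test of typical vs pandemic responses for
#' each item, with a Bonferroni-adjusted significance level computed from
#' the actual number of tested items (`alpha / n_items`; e.g. 17 items at
#' alpha 0.05 gives 0.0029). Items whose paired differences are all zero are
#' flagged degenerate and never counted significant.
#'
#' @inheritParams score_leq
#' @param alpha Family-wise significance level before correction
#'   (default 0.05).
#' @param min_pairs Minimum number of subjects with both phases per item
#'   (default 6).
#' @return Tibble with `item_id`, `n_pairs`, `statistic` (W), `p`,
#'   `degenerate`, `significant` (after Bonferroni), plus the adjusted level
#'   in the `"alpha_bonferroni"` attribute.
#' @export
item_change_tests <- function(item_table, exclusions = character(),
                              alpha = 0.05, min_pairs = 6) {
  item_table <- validate_items(item_table)
  tab <- item_table[!(item_table$item_id %in% exclusions), , drop = FALSE]
  items <- sort(unique(tab$item_id))
  if (length(items) == 0) stop("no items to test", call. = FALSE)
  alpha_adj <- alpha / length(items)

  rows <- lapply(items, function(it) {
    sub <- tab[tab$item_id == it, ]
    wide <- dplyr::inner_join(
      sub[sub$phase == "typical", c("subject_id", "response")],
      sub[sub$phase == "pandemic", c("subject_id", "response")],
      by = "subject_id", suffix = c("_typ", "_pan")
    )
    if (nrow(wide) < min_pairs) {
      stop("item ", it, " has ", nrow(wide), " paired responses; at least ",
           min_pairs, " required", call. = FALSE)
    }
    rt <- rank_tests(wide$response_typ, wide$response_pan,
                     mode = "wilcoxon-signed-rank")
    tibble::tibble(
      item_id = it, n_pairs = nrow(wide), statistic = rt$statistic,
      p = rt$p, degenerate = rt$degenerate,
      significant = !rt$degenerate && !is.na(rt$p) && rt$p < alpha_adj
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha_bonferroni") <- alpha_adj
  out
}

validate_items <- function(item_table) {
  need <- c("subject_id", "item_id", "phase", "response")
  missing_cols <- setdiff(need, names(item_table))
  if (length(missing_cols) > 0) {
    stop("item table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(item_table$response %in% 0:5))
  if (length(bad) > 0) {
    stop("responses outside the 0-5 scale at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(item_table$phase %in% c("typical", "pandemic"))) {
    stop("`phase` must be 'typical' or 'pandemic'", call. = FALSE)
  }
  tibble::as_tibble(item_table)
}
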