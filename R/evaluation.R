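#' Rating tables
#'
#' Expert ratings of candidate explanations on the 4-point Likert scale
#' (1 = not useful ... 4 = very useful), one row per (term, source,
#' rater).  A missing score (`NA`, or an empty field in the CSV format)
#' means the source provided no explanation for that term; such rows
#' never enter quality but contribute an exact 0 to usefulness.
#'
#' @param ratings data frame with columns `term`, `source`, `rater`,
#'   `score`, or a path to a CSV file with that header.
#' @return the validated data frame.
#' @export
validate_ratings <- function(ratings) {
  if (is.character(ratings) && length(ratings) == 1) {
    mg_assert(file.exists(ratings), "ratings file not found: ", ratings)
    ratings <- utils::read.csv(ratings, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8")
  }
  mg_assert(is.data.frame(ratings) &&
              all(c("term", "source", "rater", "score") %in% names(ratings)),
            "`ratings` needs columns term, source, rater, score")
  mg_assert(nrow(ratings) > 0, "empty rating table")
  ratings$score <- suppressWarnings(as.numeric(ratings$score))
  ok <- is.na(ratings$score) | (ratings$score %in% 1:4)
  if (!all(ok)) {
    mg_stop("score(s) outside the 1-4 Likert scale at row(s): ",
            paste(head(which(!ok), 10), collapse = ", "))
  }
  key <- paste(ratings$term, ratings$source, ratings$rater, sep = "\r")
  mg_assert(!anyDuplicated(key),
            "duplicate (term, source, rater) rating(s) present")
  ratings
}

# per-(term, source) score averaged across raters; NA = not covered
per_term_scores <- function(ratings) {
  agg <- stats::aggregate(score ~ term + source, data = ratings,
                          FUN = mean, na.action = stats::na.pass)
  agg
}

#' Quality, coverage and usefulness per source
#'
#' For each source: per-term score is the mean across raters;
#' \emph{quality} averages those scores over the terms the source
#' covers (1-4 scale); \emph{coverage} is covered / `n_terms`;
#' \emph{usefulness} averages over \emph{all} `n_terms` with 0
#' substituted for uncovered terms (0-4 scale), so usefulness = quality
#' x coverage exactly.
#'
#' @param ratings a rating table (see [validate_ratings()]).
#' @param n_terms total number of study terms (covered or not).
#' @return data frame with columns `source`, `quality`, `coverage`,
#'   `usefulness`, one row per source.
#' @export
compute_metrics <- function(ratings, n_terms) {
  ratings <- validate_ratings(ratings)
  mg_assert(n_terms >= 1, "`n_terms` must be >= 1")
  pts <- per_term_scores(ratings)
  out <- lapply(split(pts, pts$source), function(d) {
    covered <- d$score[!is.na(d$score)]
    mg_assert(length(covered) <= n_terms,
              "source '", d$source[1], "' covers more terms than n_terms")
    quality <- if (length(covered) > 0) mean(covered) else NA_real_
    coverage <- length(covered) / n_terms
    usefulness <- sum(covered) / n_terms
    data.frame(source = d$source[1], quality = quality, coverage = coverage,
               usefulness = usefulness, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$source, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-choice agreement indicators
#'
#' For every rater and term, the \emph{best set} is the set of sources
#' achieving that rater's maximum score for the term (several sources
#' may tie).  The conservative agreement indicator for a term is 1 when
#' all raters' best sets are identical; the liberal indicator is 1 when
#' they share at least one source.  Terms not rated by every rater are
#' excluded with a warning.
#'
#' @param ratings a rating table with at least 2 raters.
#' @param mode `"conservative"` or `"liberal"`.
#' @return data frame `term`, `agree` (0/1), plus attribute
#'   `"best_sets"` (per rater, per term).
#' @export
best_choice_indicators <- function(ratings, mode = c("conservative", "liberal")) {
  mode <- match.arg(mode)
  ratings <- validate_ratings(ratings)
  raters <- sort(unique(ratings$rater))
  mg_assert(length(raters) >= 2, "need at least 2 raters")
  # a rater has rated a term when any row exists (even an NA "no
  # explanation" row counts as having seen the term)
  seen <- unique(ratings[, c("term", "rater")])
  n_seen <- table(seen$term)
  complete <- names(n_seen)[n_seen == length(raters)]
  dropped <- setdiff(unique(ratings$term), complete)
  if (length(dropped) > 0) {
    warning("excluding ", length(dropped),
            " term(s) not rated by all raters")
  }
  best_sets <- lapply(raters, function(r) {
    d <- ratings[ratings$rater == r & ratings$term %in% complete &
                   !is.na(ratings$score), , drop = FALSE]
    lapply(split(d, d$term),
           function(dt) sort(dt$source[dt$score == max(dt$score)]))
  })
  names(best_sets) <- as.character(raters)
  agree <- vapply(sort(complete), function(tm) {
    sets <- lapply(best_sets, function(bs) bs[[tm]] %||% character())
    if (mode == "conservative") {
      all(vapply(sets[-1], identical, logical(1), sets[[1]]))
    } else {
      length(Reduce(intersect, sets)) > 0
    }
  }, logical(1))
  out <- data.frame(term = sort(complete), agree = as.integer(agree),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "best_sets") <- best_sets
  out
}

#' Cronbach's alpha
#'
#' Standard formula with raters as items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item total))`.
#' May be negative for discordant raters; an all-constant matrix (zero
#' total variance) leaves alpha undefined and is an error.
#'
#' @param item_matrix numeric matrix, raters (items) in rows, terms
#'   (cases) in columns.
#' @return alpha as a single number.
#' @export
cronbach_alpha <- function(item_matrix) {
  mg_assert(is.matrix(item_matrix) && is.numeric(item_matrix),
            "`item_matrix` must be a numeric matrix")
  k <- nrow(item_matrix)
  mg_assert(k >= 2, "need at least 2 raters (rows)")
  mg_assert(ncol(item_matrix) >= 2, "need at least 2 terms (columns)")
  mg_assert(!anyNA(item_matrix), "item matrix contains NA")
  total_var <- var(colSums(item_matrix))
  mg_assert(total_var > 0, "zero total variance: alpha undefined")
  item_vars <- apply(item_matrix, 1, var)
  (k / (k - 1)) * (1 - sum(item_vars) / total_var)
}

#' Inter-rater agreement alpha from a rating table
#'
#' Two routes are offered, since best-choice agreement can be
#' operationalized either on raw scores or on best-set membership
#' indicators.  `on = "scores"` computes alpha over the raters'
#' per-(term, source) scores (uncovered = 0).  `on = "indicators"`
#' computes it over 0/1 best-set membership per (term, source), where a
#' rater's best set is as in [best_choice_indicators()]; `mode` is kept
#' for symmetry and reported alongside the per-term agreement rate.
#'
#' @param ratings a rating table.
#' @param mode `"conservative"` or `"liberal"` (used for the agreement
#'   rate).
#' @param on `"indicators"` or `"scores"`.
#' @return list with `alpha` and `agreement_rate` (mean per-term
#'   indicator under `mode`).
#' @export
agreement_alpha <- function(ratings, mode = c("conservative", "liberal"),
                            on = c("indicators", "scores")) {
  mode <- match.arg(mode)
  on <- match.arg(on)
  ratings <- validate_ratings(ratings)
  raters <- sort(unique(ratings$rater))
  mg_assert(length(raters) >= 2, "need at least 2 raters")
  ind <- best_choice_indicators(ratings, mode)
  cells <- unique(ratings[, c("term", "source")])
  cells <- cells[order(cells$term, cells$source, method = "radix"), ,
                 drop = FALSE]
  mat <- matrix(0, nrow = length(raters), ncol = nrow(cells),
                dimnames = list(as.character(raters), NULL))
  if (on == "scores") {
    for (i in seq_along(raters)) {
      d <- ratings[ratings$rater == raters[i], , drop = FALSE]
      j <- match(paste(cells$term, cells$source, sep = "\r"),
                 paste(d$term, d$source, sep = "\r"))
      sc <- d$score[j]
      sc[is.na(sc)] <- 0
      mat[i, ] <- sc
    }
  } else {
    best <- attr(ind, "best_sets")
    for (i in seq_along(raters)) {
      bs <- best[[as.character(raters[i])]]
      mat[i, ] <- mapply(function(tm, so) {
        as.integer(so %in% (bs[[tm]] %||% character()))
      }, cells$term, cells$source)
    }
  }
  list(alpha = cronbach_alpha(mat), agreement_rate = mean(ind$agree))
}

#' Cumulative cascade metrics
#'
#' Combines explanation sources into one system, adding them in cascade
#' order.  For each cascade prefix, cumulative coverage is the fraction
#' of terms covered by at least one source in the prefix, and
#' cumulative usefulness is the mean over all terms of the
#' \emph{highest} per-term score among the prefix sources (0 when none
#' covers: when two resources both explain a term, the higher-rated
#' explanation is kept).  Both are non-decreasing along the cascade.
#'
#' @param ratings a rating table.
#' @param cascade ordered character vector of source names.
#' @param n_terms total number of study terms.
#' @return data frame `source`, `cum_coverage`, `cum_usefulness`, one
#'   row per cascade prefix.
#' @export
cumulative_metrics <- function(ratings, cascade, n_terms) {
  ratings <- validate_ratings(ratings)
  mg_assert(length(cascade) > 0, "`cascade` must be non-empty")
  unknown <- setdiff(cascade, unique(ratings$source))
  mg_assert(length(unknown) == 0,
            "unknown source name(s) in cascade: ", paste(unknown, collapse = ", "))
  mg_assert(n_terms >= 1, "`n_terms` must be >= 1")
  pts <- per_term_scores(ratings)
  terms <- unique(pts$term)
  out <- vector("list", length(cascade))
  for (i in seq_along(cascade)) {
    prefix <- cascade[seq_len(i)]
    sub <- pts[pts$source %in% prefix & !is.na(pts$score), , drop = FALSE]
    best <- tapply(sub$score, sub$term, max)
    out[[i]] <- data.frame(source = cascade[i],
                           cum_coverage = length(best) / n_terms,
                           cum_usefulness = sum(best) / n_terms,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
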