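test_that("metrics match a per-term loop oracle and the product identity", {
  set.seed(13)
  n_terms <- 60
  terms <- paste0("t", 1:n_terms)
  per_term <- list(
    srcA = replace(runif(n_terms, 1, 4), sample(n_terms, 40), NA),
    srcB = replace(runif(n_terms, 1, 4), sample(n_terms, 5), NA))
  per_term <- lapply(per_term, function(x) round(x * 2) / 2)
  ratings <- make_ratings(per_term, terms)
  m <- compute_metrics(ratings, n_terms)

  for (src in names(per_term)) {
    # independent oracle: loop over terms, average rater pairs by hand
    sub <- ratings[ratings$source == src, ]
    scores <- vapply(terms, function(tm) mean(sub$score[sub$term == tm]),
                     numeric(1))
    covered <- scores[!is.na(scores)]
    row <- m[m$source == src, ]
    expect_equal(row$quality, mean(covered))
    expect_equal(row$coverage, length(covered) / n_terms)
    expect_equal(row$usefulness, sum(covered) / n_terms)
    # exact arithmetic identity
    expect_equal(row$usefulness, row$quality * row$coverage,
                 tolerance = 1e-12)
  }

  # maximum case: full coverage, all scores 4
  full <- make_ratings(list(top = rep(4, 10)), paste0("t", 1:10))
  mt <- compute_metrics(full, 10)
  expect_equal(unlist(mt[, c("quality", "coverage", "usefulness")]),
               c(quality = 4, coverage = 1, usefulness = 4))

  expect_error(compute_metrics(ratings[0, ], 10), "empty")
  expect_error(validate_ratings(transform(full, score = 5)), "Likert")
})

test_that("metrics are invariant to row order and rater relabelling", {
  set.seed(14)
  terms <- paste0("t", 1:20)
  ratings <- make_ratings(list(s1 = round(runif(20, 2, 8)) / 2), terms)
  m0 <- compute_metrics(ratings, 25)
  m1 <- compute_metrics(ratings[sample(nrow(ratings)), ], 25)
  relab <- transform(ratings, rater = ifelse(rater == "r1", "zz", "aa"))
  m2 <- compute_metrics(relab, 25)
  expect_equal(m1, m0)
  expect_equal(m2, m0)
})

test_that("best-choice sets drive conservative and liberal agreement", {
  # two raters with identical best sets everywhere
  same <- make_ratings(list(a = c(3, 2), b = c(1, 4)), c("t1", "t2"))
  ind <- best_choice_indicators(same, "conservative")
  expect_equal(ind$agree, c(1, 1))

  # A best {wn}, B best {wn, chv}: conservative 0, liberal 1
  part <- data.frame(
    term = "t1",
    source = rep(c("wn", "chv"), each = 2),
    rater = rep(c("A", "B"), 2),
    score = c(4, 4, 2, 4),
    stringsAsFactors = FALSE)
  expect_equal(best_choice_indicators(part, "conservative")$agree, 0)
  expect_equal(best_choice_indicators(part, "liberal")$agree, 1)

  # random tables match an explicit per-term max-set comparison oracle
  set.seed(15)
  tab <- expand.grid(term = paste0("t", 1:12), source = c("x", "y", "z"),
                     rater = c("A", "B"), stringsAsFactors = FALSE)
  tab$score <- sample(1:4, nrow(tab), TRUE)
  for (mode in c("conservative", "liberal")) {
    got <- best_choice_indicators(tab, mode)
    oracle <- vapply(sort(unique(tab$term)), function(tm) {
      sets <- lapply(c("A", "B"), function(r) {
        d <- tab[tab$term == tm & tab$rater == r, ]
        sort(d$source[d$score == max(d$score)])
      })
      if (mode == "conservative") as.integer(identical(sets[[1]], sets[[2]]))
      else as.integer(length(intersect(sets[[1]], sets[[2]])) > 0)
    }, integer(1))
    expect_equal(got$agree, unname(oracle))
  }

  # a term missing for one rater is excluded with a warning
  lop <- rbind(tab, data.frame(term = "t99", source = "x", rater = "A",
                               score = 3))
  expect_warning(got <- best_choice_indicators(lop, "liberal"), "excluding")
  expect_false("t99" %in% got$term)
})

test_that("Cronbach alpha matches hand arithmetic and its edge cases", {
  # hand-computed 2 x 4 example:
  # r1 = (1,2,3,4), r2 = (2,2,4,3); item vars 5/3 and 11/12,
  # total var 17/4; alpha = 2 * (1 - (31/12)/(17/4)) = 40/51
  m <- rbind(c(1, 2, 3, 4), c(2, 2, 4, 3))
  expect_equal(cronbach_alpha(m), 40 / 51)

  # duplicated raters with nonzero variance: perfect agreement
  x <- c(1, 3, 2, 4, 4, 1)
  expect_equal(cronbach_alpha(rbind(x, x)), 1.0)

  expect_error(cronbach_alpha(rbind(rep(2, 4), rep(2, 4))), "variance")
  expect_error(cronbach_alpha(matrix(1:4, 1)), "2 raters")
})

test_that("independent raters yield alpha near zero", {
  set.seed(16)
  a <- sample(1:4, 1000, TRUE)
  b <- sample(1:4, 1000, TRUE)
  expect_lt(abs(cronbach_alpha(rbind(a, b))), 0.15)
})

test_that("agreement alpha runs on both scores and indicators", {
  set.seed(17)
  terms <- paste0("t", 1:30)
  sc <- round(runif(30, 2, 8)) / 2
  ratings <- rbind(
    make_ratings(list(x = sc), terms),
    make_ratings(list(y = rev(sc)), terms))
  res <- agreement_alpha(ratings, "conservative", on = "scores")
  expect_true(is.finite(res$alpha))
  expect_gte(res$agreement_rate, 0)
  res2 <- agreement_alpha(ratings, "liberal", on = "indicators")
  expect_true(is.finite(res2$alpha))

  # duplicated raters agree perfectly on either route
  dup <- data.frame(term = rep(terms, 4),
                    source = rep(rep(c("x", "y"), each = 30), 2),
                    rater = rep(c("A", "B"), each = 60),
                    score = rep(rep(sample(1:4, 30, TRUE), 2), 2))
  expect_equal(agreement_alpha(dup, "conservative", on = "scores")$alpha, 1.0)
  expect_equal(mean(best_choice_indicators(dup, "conservative")$agree), 1.0)
})

test_that("cumulative cascade metrics equal union/max oracles and grow", {
  # engineered overlaps: s1 covers t1-t2, s2 covers t2-t4 with higher
  # scores on the overlap
  ratings <- make_ratings(
    list(s1 = c(3, 2, NA, NA, NA), s2 = c(NA, 4, 1, 2, NA)),
    paste0("t", 1:5))
  cm <- cumulative_metrics(ratings, c("s1", "s2"), n_terms = 5)

  # base case: one source equals its own metrics row
  m1 <- compute_metrics(ratings[ratings$source == "s1", ], 5)
  expect_equal(cm$cum_coverage[1], m1$coverage)
  expect_equal(cm$cum_usefulness[1], m1$usefulness)

  # union and per-term max oracle for the full cascade
  expect_equal(cm$cum_coverage[2], 4 / 5)
  expect_equal(cm$cum_usefulness[2], (3 + 4 + 1 + 2) / 5)

  # monotone along any cascade order
  set.seed(18)
  terms <- paste0("t", 1:40)
  big <- make_ratings(
    list(a = replace(round(runif(40, 2, 8)) / 2, sample(40, 20), NA),
         b = replace(round(runif(40, 2, 8)) / 2, sample(40, 10), NA),
         c = replace(round(runif(40, 2, 8)) / 2, sample(40, 30), NA)),
    terms)
  for (casc in list(c("a", "b", "c"), c("c", "a", "b"))) {
    cmb <- cumulative_metrics(big, casc, 40)
    expect_true(all(diff(cmb$cum_coverage) >= 0))
    expect_true(all(diff(cmb$cum_usefulness) >= 0))
    # brute-force union/max at every prefix
    pts <- stats::aggregate(score ~ term + source, big, mean,
                            na.action = stats::na.pass)
    for (i in seq_along(casc)) {
      sub <- pts[pts$source %in% casc[seq_len(i)] & !is.na(pts$score), ]
      best <- tapply(sub$score, sub$term, max)
      expect_equal(cmb$cum_coverage[i], length(best) / 40)
      expect_equal(cmb$cum_usefulness[i], sum(best) / 40)
    }
  }

  expect_error(cumulative_metrics(big, c("a", "nope"), 40), "unknown source")
})
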