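test_that("frequency tables dense-rank by descending count", {
  ft <- frequency_table(data.frame(term = c("a", "b", "c", "d", "e"),
                                   count = c(100, 50, 50, 10, 1)),
                        threshold_rank = 3)
  expect_equal(ft$table$rank[match(c("a", "b", "c", "d", "e"), ft$table$term)],
               c(1, 2, 2, 3, 4))
  expect_equal(ft$threshold_count, 10)
  # threshold beyond the table falls back to the smallest count
  ft2 <- frequency_table(data.frame(term = c("a", "b"), count = c(5, 2)),
                         threshold_rank = 5000)
  expect_equal(ft2$threshold_count, 2)
  expect_error(frequency_table(data.frame(term = character(),
                                          count = numeric())), "empty")
})

test_that("difficult-term extraction uses a strict frequency cutoff", {
  set.seed(21)
  # tokens must be pure letter runs; digits would split during tokenization
  words <- paste0("w", rep(letters[1:6], each = 5), letters[1:5])
  bg <- data.frame(term = words, count = 31 - (1:30))
  w <- function(i) words[i]
  ft <- frequency_table(bg, threshold_rank = 10)  # threshold count = 21
  docs <- data.frame(
    doc_id = c("d1", "d2"),
    doc_class = c("technical", "encyclopedic"),
    text = c(paste(w(1), w(5), w(10), w(11), w(25), "neoplasm"),
             paste(w(10), w(30), w(2), "xenograft")),
    stringsAsFactors = FALSE)
  recs <- extract_difficult_terms(docs, ft)

  # brute-force oracle: strictly below the threshold term's count
  all_toks <- unique(unlist(tokenize_documents(docs$text)))
  freq_of <- function(t) if (t %in% bg$term) bg$count[bg$term == t] else 0
  oracle <- sort(all_toks[vapply(all_toks, freq_of, numeric(1)) < 21])
  expect_setequal(recs$term, oracle)

  # the threshold-ranked term itself (count == threshold) is excluded
  expect_false(w(10) %in% recs$term)
  # absent from the background list => frequency 0, always difficult
  expect_true(all(c("neoplasm", "xenograft") %in% recs$term))
  expect_equal(recs$frequency[recs$term == "neoplasm"], 0)
  # document attribution
  expect_equal(recs$source_doc[recs$term == w(25)], "d1")
  expect_equal(recs$doc_class[recs$term == w(30)], "encyclopedic")

  expect_error(extract_difficult_terms(docs[0, ], ft), "empty")
})

test_that("the difficult-term predicate is monotone in the rank threshold", {
  # a deeper rank threshold means a rarer cutoff term, so the strict
  # frequency filter can only shrink the difficult set; a term difficult
  # at rank k stays difficult at every rank below k
  set.seed(8)
  words <- paste0("v", rep(letters[1:10], each = 5), letters[1:5])
  bg <- data.frame(term = words, count = sample(1:40, 50, TRUE))
  docs <- data.frame(doc_id = "d", doc_class = "technical",
                     text = paste(words[seq(2, 50, 3)], collapse = " "))
  prev <- NULL
  for (k in c(2, 5, 10, 20, 40)) {
    cur <- extract_difficult_terms(docs, frequency_table(bg, k))$term
    if (!is.null(prev)) {
      expect_true(all(cur %in% prev), info = paste("rank", k))
    }
    prev <- cur
  }
})

test_that("tertile groups split low and high thirds deterministically", {
  recs <- data.frame(term = letters[1:9], frequency = 1:9,
                     source_doc = "d", doc_class = "technical",
                     stringsAsFactors = FALSE)
  g <- assign_frequency_groups(recs)
  expect_equal(g$freq_group[g$frequency %in% 1:3], rep("low", 3))
  expect_equal(g$freq_group[g$frequency %in% 7:9], rep("high", 3))
  expect_equal(g$freq_group[g$frequency %in% 4:6], rep("middle", 3))

  # ties: lexicographic order before slicing, matched against an
  # explicit sort-then-slice oracle
  recs2 <- data.frame(term = c("zeta", "alpha", "beta", "gamma", "eta", "mu"),
                      frequency = c(5, 5, 5, 1, 9, 5),
                      source_doc = "d", doc_class = "technical",
                      stringsAsFactors = FALSE)
  g2 <- assign_frequency_groups(recs2)
  ord <- order(recs2$frequency, recs2$term, method = "radix")
  k <- nrow(recs2) %/% 3
  oracle <- rep("middle", nrow(recs2))
  oracle[ord[seq_len(k)]] <- "low"
  oracle[ord[seq(nrow(recs2) - k + 1, nrow(recs2))]] <- "high"
  expect_equal(g2$freq_group, oracle)

  # degenerate: all equal frequencies
  recs3 <- transform(recs, frequency = 0)
  expect_warning(g3 <- assign_frequency_groups(recs3), "equal")
  expect_true(all(g3$freq_group == "middle"))

  expect_error(assign_frequency_groups(recs[1:2, ]), "at least 3")
})

test_that("balanced sampling honours class, group and document quotas", {
  set.seed(31)
  docs_tech <- sprintf("t%02d", 1:10)
  docs_enc <- sprintf("e%02d", 1:4)
  pool <- expand.grid(doc = c(docs_tech, docs_enc), i = 1:30,
                      grp = c("low", "high"), stringsAsFactors = FALSE)
  recs <- data.frame(
    term = paste0(pool$doc, "_", pool$grp, pool$i),
    frequency = ifelse(pool$grp == "low", 1, 9),
    source_doc = pool$doc,
    doc_class = ifelse(startsWith(pool$doc, "t"), "technical", "encyclopedic"),
    freq_group = pool$grp, stringsAsFactors = FALSE)

  s <- balanced_sample(recs, n_per_class = 200, seed = 11)
  expect_equal(nrow(s), 400)
  expect_equal(as.vector(table(s$doc_class)), c(200, 200))
  tab <- table(s$doc_class, s$freq_group)
  expect_true(all(tab[, c("low", "high")] == 100))
  expect_false(any(duplicated(s$term)))
  # per-document counts differ by at most 1 within a class
  for (cl in unique(s$doc_class)) {
    counts <- table(s$source_doc[s$doc_class == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  # reproducible under the seed
  expect_identical(s, balanced_sample(recs, 200, seed = 11))
  expect_false(identical(s$term, balanced_sample(recs, 200, seed = 12)$term))

  expect_equal(nrow(balanced_sample(recs, 0)), 0)
  # a document lacking one group is compensated from its other group
  onesided <- recs[!(recs$source_doc == "t01" & recs$freq_group == "low"), ]
  s2 <- balanced_sample(onesided, 200, seed = 1)
  expect_true(all(s2$freq_group[s2$source_doc == "t01"] == "high"))
  expect_equal(sum(s2$freq_group[s2$doc_class == "technical"] == "low"), 100)
  # a near-empty document makes the within-1 balance infeasible
  thin <- recs[recs$source_doc != "t01" |
                 recs$term == recs$term[recs$source_doc == "t01"][1], ]
  expect_error(balanced_sample(thin, 200, seed = 1), "t01")
})
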