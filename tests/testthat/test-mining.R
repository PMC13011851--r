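toy3 <- function() toy_corpus(list(t1 = c("A1", "B1"), t2 = "A1", t3 = c("A1", "C1")))

test_that("frequency table counts usages under both denominator conventions", {
  ft <- frequency_table(toy3(), "total_usages")
  expect_equal(ft$code, c("A1", "B1", "C1"))
  expect_equal(ft$count, c(3L, 1L, 1L))
  expect_equal(ft$percent, c(60, 20, 20))
  expect_equal(attr(ft, "denominator"), 5)

  ft2 <- frequency_table(toy3(), "n_transactions")
  expect_equal(ft2$percent[ft2$code == "A1"], 100)

  single <- frequency_table(toy_corpus(list(t1 = "A1")))
  expect_equal(nrow(single), 1L)
  expect_equal(single$count, 1L)
})

test_that("co-occurrence matrix is symmetric with per-item diagonal and count bounds", {
  m <- cooccurrence_matrix(toy3())
  expect_true(isSymmetric(m))
  expect_equal(m["A1", "B1"], 1L)
  expect_equal(m["A1", "C1"], 1L)
  expect_equal(m["B1", "C1"], 0L)
  expect_equal(m["A1", "A1"], 3L)

  # singletons only: all off-diagonals zero
  m2 <- cooccurrence_matrix(toy_corpus(list(t1 = "A1", t2 = "B1")))
  expect_equal(sum(m2) - sum(diag(m2)), 0L)

  # identical pair everywhere: off-diagonal equals both diagonals
  m3 <- cooccurrence_matrix(toy_corpus(setNames(rep(list(c("A1", "B1")), 5),
                                                paste0("t", 1:5))))
  expect_equal(m3["A1", "B1"], 5L)
  expect_equal(diag(m3), c(A1 = 5L, B1 = 5L))

  # upper bound: co-count never exceeds either diagonal
  co <- random_corpus(30, 8, seed = 4)
  m4 <- cooccurrence_matrix(co)
  expect_true(all(m4 <= pmin(outer(diag(m4), rep(1, ncol(m4))),
                             outer(rep(1, nrow(m4)), diag(m4)))))
  expect_equal(diag(m4)[frequency_table(co)$code],
               setNames(frequency_table(co)$count, frequency_table(co)$code))
})

test_that("frequent itemsets match exhaustive enumeration and are downward closed", {
  fi <- frequent_itemsets(toy3(), min_support = 0.5, max_size = 2)
  expect_equal(itemset_keys(fi$items), "A1")
  expect_equal(fi$support, 1)

  # limit case: min_support -> 0+ yields every itemset present in >= 1 transaction
  fi0 <- frequent_itemsets(toy3(), min_support = 1e-9, max_size = 3)
  expect_equal(itemset_keys(fi0$items),
               itemset_keys(lapply(oracle_itemsets(toy3(), 1e-9, 3), `[[`, "items")))

  for (seed in 1:10) {
    co <- random_corpus(n = 25, n_items = 10, p = 0.35, seed = seed)
    fi <- frequent_itemsets(co, min_support = 0.2, max_size = 3)
    oracle <- oracle_itemsets(co, 0.2, 3)
    expect_equal(itemset_keys(fi$items), itemset_keys(lapply(oracle, `[[`, "items")))
    # anti-monotonicity: every subset of an emitted set is emitted with >= support
    keys <- vapply(fi$items, paste, "", collapse = "+")
    for (i in seq_len(nrow(fi))) {
      s <- fi$items[[i]]
      if (length(s) == 1) next
      for (j in seq_along(s)) {
        k <- paste(s[-j], collapse = "+")
        expect_true(k %in% keys)
        expect_gte(fi$support[keys == k], fi$support[i])
      }
    }
  }
})

test_that("association rules reproduce the printed top-rule arithmetic from back-solved counts", {
  # 46 transactions: 29 with both ST36 and CV12, 12 ST36 only, 3 CV12 only,
  # 2 with neither (a filler point keeps them non-empty)
  sets <- c(rep(list(c("ST36", "CV12")), 29), rep(list("ST36"), 12),
            rep(list("CV12"), 3), rep(list("GB34"), 2))
  co <- acu_corpus(setNames(sets, sprintf("t%02d", 1:46)))
  ru <- association_rules(co, min_support = 0.20, min_confidence = 0.80)
  r <- format_rules(ru)
  row <- r[r$antecedent == "CV12" & r$consequent == "ST36", ]
  expect_equal(row$support, 69.57)             # 32/46
  expect_equal(row$confidence, 90.63)          # 29/32
  expect_equal(row$expected_confidence, 89.13) # 41/46
  expect_equal(row$lift, 1.02)
})

test_that("rule metric identities: perfect confidence, independence, lift consistency", {
  # antecedent implies consequent in every transaction -> confidence 100
  co <- toy_corpus(list(t1 = c("A1", "B1"), t2 = c("A1", "B1"), t3 = "B1", t4 = "C1"))
  ru <- association_rules(co, min_support = 0.25, min_confidence = 0.5)
  expect_equal(ru$confidence[ru$antecedent == "A1" & ru$consequent == "B1"], 100)

  # independence: co-count equal to expectation -> lift exactly 1
  sets <- c(rep(list(c("A1", "B1")), 1), rep(list("A1"), 1),
            rep(list("B1"), 1), rep(list("C1"), 1))
  ind <- acu_corpus(setNames(sets, paste0("t", 1:4)))  # P(AB)=1/4=P(A)P(B)
  ru2 <- association_rules(ind, min_support = 0.2, min_confidence = 0.2)
  expect_equal(ru2$lift[ru2$antecedent == "A1" & ru2$consequent == "B1"], 1)

  # every emitted rule: lift * expected_confidence == confidence (machine precision)
  co3 <- random_corpus(40, 9, seed = 11)
  ru3 <- association_rules(co3, 0.15, 0.5, max_antecedent = 2)
  expect_equal(ru3$lift * ru3$expected_confidence, ru3$confidence, tolerance = 1e-12)
  ft <- frequency_table(co3, "n_transactions")
  expect_equal(ru3$expected_confidence,
               ft$percent[match(ru3$consequent, ft$code)], tolerance = 1e-12)
})

test_that("rules match exhaustive enumeration on random corpora", {
  for (seed in 1:10) {
    co <- random_corpus(n = 30, n_items = 9, p = 0.35, seed = 100 + seed)
    ru <- association_rules(co, 0.2, 0.7, max_antecedent = 2)
    got <- sort(paste(ru$antecedent, ru$consequent, sep = "=>"))
    expect_equal(got, oracle_rules(co, 0.2, 0.7, 2))
  }
})

test_that("rule_lift reproduces printed coefficients and errors on zero support", {
  expect_equal(rule_lift(90.63, 89.13, digits = 2), 1.02)
  expect_equal(rule_lift(100.00, 69.57, digits = 2), 1.44)
  expect_equal(rule_lift(55, 55, digits = 2), 1)
  expect_error(rule_lift(50, 0), "positive")
})

test_that("round_half_up rounds away from zero at the boundary", {
  # 0.125 is exactly representable; round() would give 0.12 (half-even)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
})
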