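dv <- toy_drug_vocab()
av <- toy_ade_vocab()
rules <- extraction_rules()

toy_universe <- function() {
  build_universe(extract_mentions(toy_corpus(), rules, dv, av))
}

test_that("the universe keeps exactly the articles with both mention kinds", {
  m <- extract_mentions(toy_corpus(), rules, dv, av)
  u <- build_universe(m)
  expect_setequal(u$article_ids, c("A1", "A2", "A3", "A7"))
  # all-complete corpus: universe equals the corpus
  cp <- corpus(list(B1 = list(c("T_oflox", "AE"), c("tendinopathy", "CI")),
                    B2 = list(c("T_rosuva", "AE"), c("dili", "CI"))))
  u2 <- build_universe(extract_mentions(cp, rules, dv, av))
  expect_setequal(u2$article_ids, c("B1", "B2"))
  # a corpus with no complete article has no universe
  cp3 <- corpus(list(C1 = list(c("T_oflox", "AE"))))
  expect_error(build_universe(extract_mentions(cp3, rules, dv, av)),
               "empty universe")
})

test_that("contingency matches direct enumeration on the {de},{d},{e},{} universe", {
  cp <- corpus(list(
    U1 = list(c("T_oflox", "AE"), c("tendinopathy", "CI")),
    U2 = list(c("T_oflox", "AE"), c("dili", "CI")),
    U3 = list(c("T_cipro", "AE"), c("tendinopathy", "CI")),
    U4 = list(c("T_cipro", "AE"), c("dili", "CI"))))
  u <- build_universe(extract_mentions(cp, rules, dv, av))
  tab <- contingency(u, has_drug(u, "oflox"), has_ade(u, "tendinopathy"))
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
  # function predicates agree with vector predicates
  tab2 <- contingency(u,
                      function(id) id %in% c("U1", "U2"),
                      function(id) id %in% c("U1", "U3"))
  expect_equal(c(tab2$a, tab2$b, tab2$c, tab2$d), c(1, 1, 1, 1))
})

test_that("every 2x2 table partitions the universe", {
  u <- toy_universe()
  n <- length(u$article_ids)
  for (ing in u$ingredients) for (term in u$ade_terms) {
    tab <- contingency(u, has_drug(u, ing), has_ade(u, term))
    expect_equal(tab$a + tab$b + tab$c + tab$d, n)
  }
})

test_that("a single-drug class has the same tables as its drug", {
  u <- toy_universe()
  solo <- list(SOLO = "rosuva")
  class_recs <- signal_scan(u, "class_x_ade", class_members = solo)
  drug_recs <- signal_scan(u, "drug_x_ade")
  drug_recs <- drug_recs[drug_recs$row_id == "rosuva", ]
  expect_equal(class_recs[, c("col_id", "a", "b", "c", "d", "prr")],
               drug_recs[, c("col_id", "a", "b", "c", "d", "prr")],
               ignore_attr = TRUE)
})

test_that("PRR follows the 2x2 definition with the 0.5 zero-cell branch", {
  expect_equal(prr(list(a = 10, b = 90, c = 100, d = 900))$prr, 1.0)
  res <- prr(list(a = 5, b = 0, c = 20, d = 975))
  expect_true(res$corrected)
  expect_equal(res$table$a, 5.5)
  expect_equal(res$prr, (5.5 / 6) / (20.5 / 996), tolerance = 1e-12)
  expect_equal(res$prr, 44.5, tolerance = 0.01)
  # c = 0 also triggers the correction
  expect_true(prr(list(a = 3, b = 7, c = 0, d = 10))$corrected)
  expect_false(prr(list(a = 3, b = 7, c = 1, d = 9))$corrected)
  expect_error(prr(list(a = 0, b = 0, c = 5, d = 5)), "undefined")
})

test_that("signal scans agree with the brute-force article counter at all levels", {
  set.seed(101)
  ade_map <- list()
  for (tm in ade_terms(av)) ade_map[[tm]] <- aggregate_ade(av, tm)
  for (rep in 1:4) {
    n <- sample(10:50, 1)
    terms <- c("T_oflox", "T_cipro", "T_levo", "T_moxi", "T_rosuva",
               "T_atorva", "T_simva", "T_valproic_acid")
    ades <- c("tendinopathy", "rhabdomyolysis", "dili")
    recs <- lapply(seq_len(n), function(i) {
      anns <- list()
      for (tm in sample(terms, sample(0:2, 1)))
        anns <- c(anns, list(c(tm, "AE")))
      for (ad in sample(ades, sample(0:2, 1)))
        anns <- c(anns, list(c(ad, "CI")))
      anns
    })
    names(recs) <- sprintf("R%03d", seq_len(n))
    keep <- vapply(recs, length, integer(1)) > 0
    cp <- corpus(recs[keep])
    m <- extract_mentions(cp, rules, dv, av)
    if (length(setdiff(cp$article_ids, m$incomplete)) == 0L) next
    u <- build_universe(m)
    sets <- bf_article_sets(cp, rules, dv, av)
    members <- eligible_classes(u$ingredients, dv, min_members = 2)

    for (lv in c("drug_x_ade", "drug_x_ade_class", "class_x_ade",
                 "class_x_ade_class")) {
      recs_lv <- signal_scan(u, lv, ade_vocab = av, class_members = members)
      expect_true(all(recs_lv$a >= 1))
      for (i in seq_len(nrow(recs_lv))) {
        row_ids <- if (startsWith(lv, "class")) members[[recs_lv$row_id[i]]]
          else recs_lv$row_id[i]
        col_is_class <- endsWith(lv, "ade_class")
        col_ids <- recs_lv$col_id[i]
        bft <- bf_table(sets, row_ids, col_ids,
                        ade_map = if (col_is_class) ade_map else NULL)
        expect_equal(unname(c(recs_lv$a[i], recs_lv$b[i], recs_lv$c[i],
                              recs_lv$d[i])), unname(bft),
                     info = paste(lv, recs_lv$row_id[i], recs_lv$col_id[i]))
        expect_equal(recs_lv$prr[i],
                     bf_prr(bft[1], bft[2], bft[3], bft[4]),
                     tolerance = 1e-12)
      }
      # record count equals the brute-force count of co-occurring pairs
      bf_pairs <- 0L
      row_sets <- if (startsWith(lv, "class")) members else
        setNames(as.list(u$ingredients), u$ingredients)
      col_sets <- if (endsWith(lv, "ade_class")) {
        cls <- unique(unlist(ade_map[u$ade_terms]))
        setNames(lapply(cls, function(cl)
          names(Filter(function(x) cl %in% x, ade_map))), cls)
      } else setNames(as.list(u$ade_terms), u$ade_terms)
      for (rs in row_sets) for (cs in col_sets) {
        if (bf_table(sets, rs, cs)[1] >= 1) bf_pairs <- bf_pairs + 1L
      }
      expect_equal(nrow(recs_lv), bf_pairs, info = lv)
    }
  }
})

test_that("PRR is invariant under article reordering", {
  cp <- toy_corpus()
  perm <- rev(cp$article_ids)
  recs <- setNames(lapply(perm, function(id) {
    ann <- cp$annotations[cp$annotations$article_id == id, ]
    lapply(seq_len(nrow(ann)), function(i)
      c(ann$descriptor_id[i],
        strsplit(ann$qualifiers[i], ",", fixed = TRUE)[[1L]]))
  }), perm)
  u1 <- build_universe(extract_mentions(cp, rules, dv, av))
  u2 <- build_universe(extract_mentions(corpus(recs), rules, dv, av))
  s1 <- signal_scan(u1, "drug_x_ade")
  s2 <- signal_scan(u2, "drug_x_ade")
  expect_equal(s1, s2)
})

test_that("dense matrices hold ln(1) = 0 for absent pairs and exact logs otherwise", {
  empty <- data.frame(level = character(), row_id = character(),
                      col_id = character(), a = numeric(), b = numeric(),
                      c = numeric(), d = numeric(), corrected = logical(),
                      prr = numeric(), log_prr = numeric())
  m0 <- to_matrix(empty, row_ids = c("r1", "r2"), col_ids = "c1")
  expect_true(all(m0 == 0))
  one <- data.frame(level = "drug_x_ade", row_id = "r1", col_id = "c1",
                    a = 1, b = 1, c = 1, d = 1, corrected = FALSE,
                    prr = exp(1), log_prr = 1, stringsAsFactors = FALSE)
  expect_equal(to_matrix(one)["r1", "c1"], 1.0)
  expect_error(to_matrix(rbind(one, one)), "duplicate")

  u <- toy_universe()
  recs <- signal_scan(u, "drug_x_ade")
  m <- to_matrix(recs, row_ids = u$ingredients, col_ids = u$ade_terms)
  for (i in seq_len(nrow(recs)))
    expect_equal(m[recs$row_id[i], recs$col_id[i]], log(recs$prr[i]),
                 tolerance = 1e-12)
})
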