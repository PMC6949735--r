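test_that("hypergeometric tail reproduces hand-computable cases", {
  # N = 10, K = 5, n = 5, k = 5: 1 / C(10, 5) = 1/252
  ann <- data.frame(subject_id = letters[1:5], term_id = "t1",
                    stringsAsFactors = FALSE)
  u <- term_universe(ann, background = letters[1:10])
  res <- hypergeom_enrich(letters[1:5], u)
  expect_equal(res$k, 5)
  expect_equal(res$p_value, 1 / choose(10, 5))

  # term covering the whole background is certain: p = 1
  full <- term_universe(data.frame(subject_id = letters[1:6], term_id = "all"),
                        background = letters[1:6])
  rf <- hypergeom_enrich(letters[1:3], full)
  expect_equal(rf$k, rf$n)
  expect_equal(rf$p_value, 1)

  # empty query: every p is 1
  rq <- hypergeom_enrich(character(0), u)
  expect_true(all(rq$p_value == 1))

  expect_error(term_universe(ann, background = character(0)), "background")
})

test_that("tail probability equals exhaustive enumeration for all N <= 12", {
  for (N in 2:12) {
    bg <- sprintf("s%02d", 1:N)
    for (n in 1:N) {
      draws <- utils::combn(N, n) # every possible query of size n
      for (K in 1:(N - 1)) {
        u <- term_universe(data.frame(subject_id = bg[1:K], term_id = "t"),
                           background = bg)
        overlaps <- colSums(matrix(draws <= K, nrow = n))
        for (k in max(0, n + K - N):min(K, n)) {
          # a query with exactly k members inside the term
          query <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
          res <- hypergeom_enrich(query, u)
          expect_equal(res$p_value, mean(overlaps >= k),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("p is non-increasing in the overlap for fixed N, K, n", {
  N <- 40; K <- 12; n <- 10
  bg <- sprintf("s%02d", 1:N)
  u <- term_universe(data.frame(subject_id = bg[1:K], term_id = "t"),
                     background = bg)
  ps <- vapply(0:min(K, n), function(k) {
    query <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
    hypergeom_enrich(query, u)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("out-of-background query ids are dropped with a warning", {
  u <- term_universe(data.frame(subject_id = letters[1:4], term_id = "t"),
                     background = letters[1:8])
  expect_warning(res <- hypergeom_enrich(c("a", "zz"), u), "dropped")
  expect_equal(res$n, 1)
  expect_equal(attr(res, "n_dropped"), 1)
})

test_that("EASE-style correction is more conservative and BH q-values appear", {
  bg <- sprintf("s%02d", 1:30)
  ann <- data.frame(subject_id = bg[1:8], term_id = "t")
  u <- term_universe(ann, background = bg)
  raw <- hypergeom_enrich(bg[1:6], u)
  ease <- hypergeom_enrich(bg[1:6], u, ease = TRUE)
  expect_gt(ease$p_value, raw$p_value)

  multi <- rbind(ann, data.frame(subject_id = bg[5:20], term_id = "t2"))
  um <- term_universe(multi, background = bg)
  rf <- hypergeom_enrich(bg[1:6], um, fdr = TRUE)
  expect_true("q_value" %in% names(rf))
  expect_true(all(rf$q_value >= rf$p_value - 1e-12))
})

test_that("results sort by p with term-id tie-break and flag significance", {
  bg <- sprintf("s%02d", 1:20)
  ann <- rbind(data.frame(subject_id = bg[1:5], term_id = "zeta"),
               data.frame(subject_id = bg[1:5], term_id = "alpha"),
               data.frame(subject_id = bg[11:18], term_id = "mid"))
  u <- term_universe(ann, background = bg)
  res <- hypergeom_enrich(bg[1:5], u)
  # identical member sets tie exactly; alphabetical order breaks the tie
  expect_equal(res$term_id[1:2], c("alpha", "zeta"))
  expect_equal(res$significant, res$p_value < 0.05)
})

test_that("function-module grouping is additive with a default bucket", {
  bg <- sprintf("T%02d", 1:40)
  ann <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(subject_id = bg[seq_len(6 + i)], term_id = sprintf("pw%02d", i))
  }))
  u <- term_universe(ann, background = bg)
  res <- hypergeom_enrich(bg[1:10], u)
  mm <- data.frame(
    subject_id = sprintf("pw%02d", 1:8),
    term_id = rep(c("inflammatory regulation", "immune regulation",
                    "metabolic regulation", "bacterial infection or mycosis"),
                  each = 2), stringsAsFactors = FALSE)
  grp <- group_by_function_module(res, mm)
  expect_equal(sum(grp$n_terms), nrow(res))
  # the five canonical labels all appear
  expect_setequal(grp$module,
                  c("inflammatory regulation", "immune regulation",
                    "metabolic regulation", "bacterial infection or mycosis",
                    "other function"))
  # the two unmapped pathways land in "other function"
  expect_equal(grp$n_terms[grp$module == "other function"], 2)
  # pooled target sets are unions of per-term hits
  infl <- grp$targets[[which(grp$module == "inflammatory regulation")]]
  expect_setequal(infl,
                  unique(unlist(res$hits[res$term_id %in% c("pw01", "pw02")])))

  # empty results: five modules, all-zero counts
  grp0 <- group_by_function_module(res[0, ], mm)
  expect_equal(nrow(grp0), 5)
  expect_true(all(grp0$n_terms == 0))

  # a pathway in two modules violates the function requirement
  bad <- rbind(mm, data.frame(subject_id = "pw01", term_id = "other function"))
  expect_error(group_by_function_module(res, bad), "more than one")
})
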