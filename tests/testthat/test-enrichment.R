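# Hypergeometric term-for-term analysis, BH adjustment, subset comparison.

# Small deterministic query: 20-gene population, 5-gene study, one term
# annotating 5 population genes of which 4 are in the study.
worked_query <- function() {
  population <- sprintf("g%02d", 1:20)
  study <- population[1:5]
  anns <- annotation_set(data.frame(
    gene = c(population[1:4], population[6],       # K=5, k=4
             population[10:12]),                   # K=3, k=0
    term = c(rep("GO:A", 5), rep("GO:B", 3))))
  list(population = population, study = study, anns = anns)
}

test_that("raw p-values equal the exact enumeration, including the worked value", {
  q <- worked_query()
  tab <- term_for_term(q$study, q$population, q$anns)
  a <- tab[tab$term_id == "GO:A", ]
  expect_equal(a$K, 5L)
  expect_equal(a$k, 4L)
  # C(5,4)C(15,1) + C(5,5)C(15,0) over C(20,5) = 76/15504
  expect_equal(a$raw_p, 76 / 15504, tolerance = 1e-12)
  expect_equal(a$raw_p, oracle_hyper_upper(20, 5, 5, 4), tolerance = 1e-12)
  # k = 0 has upper-tail probability 1
  expect_equal(tab$raw_p[tab$term_id == "GO:B"], 1)
})

test_that("raw p-values match the enumeration oracle across all small configurations", {
  for (N in c(5L, 12L, 20L, 30L)) {
    for (K in unique(c(1L, N %/% 3L, N %/% 2L, N - 1L))) {
      for (n in unique(c(1L, N %/% 4L, N %/% 2L))) {
        for (k in 0:min(K, n)) {
          expect_equal(
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            oracle_hyper_upper(N, K, n, k),
            tolerance = 1e-10,
            label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("BH adjustment reproduces hand step-up values and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 1.0)), c(0.10, 1.0))
  # monotone over sorted input, never below raw
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))  # all equal: unchanged
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("rows are sorted by raw p then term id, and the query is validated", {
  q <- worked_query()
  tab <- term_for_term(q$study, q$population, q$anns)
  expect_equal(tab$term_id, c("GO:A", "GO:B"))
  expect_true(all(tab$adjusted_p >= tab$raw_p))
  expect_true(all(tab$k <= pmin(tab$K, tab$n)))
  expect_error(term_for_term(c(q$study, "stranger"), q$population, q$anns),
               "stranger")
})

test_that("untestable terms are dropped before correction and reported", {
  q <- worked_query()
  expect_message(
    tab <- term_for_term(q$study, q$population, q$anns,
                         terms = c("GO:A", "GO:B", "GO:UNSEEN")),
    "1 untestable")
  expect_setequal(tab$term_id, c("GO:A", "GO:B"))
})

test_that("clipping a term set leaves raw p-values untouched and only moves adjusted ones", {
  q <- worked_query()
  full <- term_for_term(q$study, q$population, q$anns, label = "full")
  clipped <- term_for_term(q$study, q$population, q$anns,
                           terms = "GO:A", label = "clipped")
  a_full <- full[full$term_id == "GO:A", ]
  a_clip <- clipped[clipped$term_id == "GO:A", ]
  expect_identical(a_full$raw_p, a_clip$raw_p)
  # m drops from 2 to 1, so the BH multiplier relaxes
  expect_equal(a_full$adjusted_p, min(1, 2 * a_full$raw_p))
  expect_equal(a_clip$adjusted_p, a_clip$raw_p)
  expect_true(a_clip$adjusted_p <= a_full$adjusted_p)
})

test_that("annotation propagation follows the true-path rule", {
  dag <- t6_dag()
  anns <- annotation_set(data.frame(gene = c("g1", "g2", "g3"),
                                    term = c("D", "D", "R")))
  population <- c("g1", "g2", "g3", "g4")
  study <- c("g1", "g2")
  plain <- term_for_term(study, population, anns)
  prop <- term_for_term(study, population, anns, propagate = TRUE,
                        dag = dag)
  # D's ancestors (C, A, R and the part_of target B) inherit its genes
  expect_setequal(prop$term_id, c("A", "B", "C", "D", "R"))
  expect_equal(prop$K[prop$term_id == "C"], 2L)
  expect_equal(prop$K[prop$term_id == "R"], 3L)  # its own gene + D's two
  # counts never decrease under propagation
  shared <- intersect(plain$term_id, prop$term_id)
  expect_true(all(prop$K[match(shared, prop$term_id)] >=
                    plain$K[match(shared, plain$term_id)]))
})

test_that("subset comparison partitions passing terms and tallies lower adjusted p-values", {
  # hand-built tables over the same query via explicit gene-set lists
  population <- sprintf("g%02d", 1:30)
  study <- population[1:6]
  sets <- list(t1 = population[1:6], t2 = population[c(1:5, 10)],
               t3 = population[7:12], t4 = population[c(1, 2, 20:25)])
  full <- term_for_term(study, population, sets, label = "full")
  clip <- term_for_term(study, population, sets[c("t1", "t2")],
                        label = "clip")
  rep <- compare_subsets(list(full = full, clip = clip), cutoff = 0.05)
  expect_s3_class(rep, "subset_comparison")
  passing <- attr(rep, "passing")
  expect_true(all(passing$clip %in% c("t1", "t2")))
  # shared terms: tallies count strictly lower adjusted p's on each side
  expect_true(rep$lower_adj_a + rep$lower_adj_b <= rep$shared)

  # identical tables share everything and win nothing strictly
  rep2 <- compare_subsets(list(a = full, b = full), cutoff = 0.05)
  expect_equal(rep2$unique_a, 0L)
  expect_equal(rep2$unique_b, 0L)
  expect_equal(rep2$lower_adj_a, 0L)
  expect_equal(rep2$lower_adj_b, 0L)

  # mismatched queries are rejected
  other <- term_for_term(population[7:10], population, sets)
  expect_error(compare_subsets(list(a = full, b = other), cutoff = 0.05),
               "different query")
})

test_that("unique-to-subset terms split into flagged vs parental when clip results are given", {
  dag <- t6_dag()
  clipres <- clip_ontology(dag, "D")$result
  population <- sprintf("g%02d", 1:20)
  study <- population[1:4]
  sets <- list(D = population[1:4], B = population[c(1:3, 10)],
               E = population[11:14])
  full <- term_for_term(study, population, sets, label = "full")
  sub <- term_for_term(study, population, sets[c("D", "B")],
                       label = "sub")
  rep <- compare_subsets(list(full = full, sub = sub), cutoff = 0.2,
                         clip_results = list(sub = clipres))
  # terms unique to `sub` are classified against its clip provenance
  expect_true(is.na(rep$unique_a_flagged))  # no clip result for 'full'
  expect_equal(rep$unique_b_flagged + rep$unique_b_parental,
               rep$unique_b)
})

test_that("a planted low-p term usually improves its adjusted p under a half-clipped subset", {
  set.seed(101)
  m <- 40L
  wins <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    raw <- c(planted = 0.001, runif(m - 1L))
    adj_full <- bh_adjust(raw)[1]
    keep <- c(1L, sample(2:m, (m - 1L) %/% 2L))
    adj_clip <- bh_adjust(raw[keep])[1]
    if (adj_clip <= adj_full) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.9)
})
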