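# Ancestor closure and the clipping operations.

test_that("closure on the seven-term fixture follows each relation role correctly", {
  dag <- t6_dag()
  # part_of pulls in B one step; is_a closes to the root; the regulates
  # edge D -> X is never followed
  expect_equal(ancestor_closure(dag, "D"), c("A", "B", "C", "D", "R"))
  # empty seeds, empty closure
  expect_equal(ancestor_closure(dag, character()), character(0))
  # demoting part_of to ignored drops B
  no_po <- traversal_policy(one_step = character(),
                            ignored = c("part_of", "regulates",
                                        "positively_regulates",
                                        "negatively_regulates"))
  expect_equal(ancestor_closure(dag, "D", no_po), c("A", "C", "D", "R"))
  # one-step relations are not followed from non-seed members: E's
  # closure reaches B and R but never D's part_of target
  expect_equal(ancestor_closure(dag, "E"), c("B", "E", "R"))
})

test_that("closure rejects unknown and obsolete seeds by name", {
  dag <- t6_dag()
  expect_error(ancestor_closure(dag, c("D", "NOPE")), "NOPE")
  obs <- ontology_dag(data.frame(id = c("A", "Z"),
                                 obsolete = c(FALSE, TRUE)))
  expect_error(ancestor_closure(obs, "Z"), "obsolete")
})

test_that("clipping the fixture at one flagged term keeps exactly its policy ancestors", {
  clipped <- clip_ontology(t6_dag(), "D")
  expect_equal(sort(clipped$dag$terms$id), c("A", "B", "C", "D", "R"))
  expect_equal(clipped$result$flagged, "D")
  expect_equal(clipped$result$parental, c("A", "B", "C", "R"))
  expect_equal(clipped$result$removed, c("E", "X"))
  # edges with a removed endpoint are gone; the rest survive untouched
  expect_false(any(clipped$dag$edges$child == "E"))
  expect_false(any(clipped$dag$edges$relation == "regulates"))
  expect_true(any(clipped$dag$edges$relation == "part_of"))
  # provenance labels flagged vs parental
  expect_equal(unname(clipped$result$provenance[["D"]]), "flagged")
  expect_equal(unname(clipped$result$provenance[["B"]]), "parental")
})

test_that("degenerate clips behave: identity, empty, absent id", {
  dag <- t6_dag()
  all_ids <- dag$terms$id
  full <- clip_ontology(dag, all_ids)
  expect_setequal(full$dag$terms$id, all_ids)
  expect_length(full$result$parental, 0L)
  expect_length(full$result$removed, 0L)

  none <- clip_ontology(dag, character())
  expect_equal(nrow(none$dag$terms), 0L)
  expect_setequal(none$result$removed, all_ids)

  expect_error(clip_ontology(dag, "MISSING"), "MISSING")
})

test_that("organism clip flags directly annotated terms and composes with closure", {
  dag <- t6_dag()
  clipped <- organism_clip(dag, t6_annotations())
  expect_setequal(clipped$dag$terms$id, c("A", "B", "C", "D", "R"))
  expect_equal(clipped$result$flagged, "D")
  expect_length(clipped$result$parental, 4L)
  expect_equal(unname(clipped$result$provenance[["D"]]), "organism")

  # empty record table: everything removed
  empty <- organism_clip(dag, annotation_set(
    data.frame(gene = character(), term = character())))
  expect_equal(nrow(empty$dag$terms), 0L)
  expect_setequal(empty$result$removed, dag$terms$id)

  # every term annotated: nothing parental, nothing removed
  all_ann <- annotation_set(data.frame(gene = "g1", term = dag$terms$id))
  total <- organism_clip(dag, all_ann)
  expect_setequal(total$dag$terms$id, dag$terms$id)
  expect_length(total$result$parental, 0L)

  # empty *list* of annotation sets is an error, unlike empty sets
  expect_error(organism_clip(dag, list()), "non-empty")
  # annotation term ids missing from the dag are skipped with a warning
  lagging <- annotation_set(data.frame(gene = "g1",
                                       term = c("D", "GO:9999999")))
  expect_warning(res <- organism_clip(dag, lagging), "GO:9999999")
  expect_equal(res$result$flagged, "D")
})

test_that("closure agrees with the matrix-reachability oracle on random DAGs", {
  set.seed(42)
  for (rep in 1:60) {
    dag <- random_test_dag(n = sample(10:60, 1))
    seeds <- sample(dag$terms$id, sample(1:5, 1))
    expect_identical(ancestor_closure(dag, seeds),
                     oracle_closure(dag, seeds))
    # and under a policy where part_of is transitive too
    pol <- traversal_policy(transitive = c("is_a", "part_of"),
                            one_step = character())
    expect_identical(ancestor_closure(dag, seeds, pol),
                     oracle_closure(dag, seeds, pol))
  }
})

test_that("clip is idempotent, monotone and validity-preserving on random inputs", {
  set.seed(7)
  for (rep in 1:30) {
    dag <- random_test_dag(n = sample(15:50, 1))
    f2 <- sample(dag$terms$id, sample(2:8, 1))
    f1 <- sample(f2, max(1L, length(f2) %/% 2L))

    c1 <- clip_ontology(dag, f1)
    c2 <- clip_ontology(dag, f2)
    # monotone: a larger flagged set retains a superset
    expect_true(all(c1$dag$terms$id %in% c2$dag$terms$id))
    # decomposition: flagged + parental = retained, disjoint
    expect_length(intersect(c2$result$flagged, c2$result$parental), 0L)
    expect_equal(length(c2$result$flagged) + length(c2$result$parental),
                 nrow(c2$dag$terms))
    # idempotent: reclipping the clipped graph changes nothing
    again <- clip_ontology(c2$dag, f2)
    expect_same_ontology(again$dag, c2$dag)
    # consistency: clipped graph still validates; all is_a ancestors kept
    expect_true(is_valid_ontology(validate_ontology(c2$dag)))
    isa <- c2$dag$edges[c2$dag$edges$relation == "is_a", ]
    expect_true(all(isa$parent %in% c2$dag$terms$id))
  }
})
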