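toy_dag <- function() {
  load_obo(c("format-version: 1.2",
             "default-namespace: biological_process", "",
             "[Term]", "id: GO:0000001", "name: root", "",
             "[Term]", "id: GO:0000002", "is_a: GO:0000001", "",
             "[Term]", "id: GO:0000003", "is_a: GO:0000002", "",
             "[Term]", "id: GO:0000004", "is_a: GO:0000002"),
           text = TRUE)
}

gaf_line <- function(protein, term, evidence, qualifier = "enables") {
  paste("DB", protein, protein, qualifier, term, "REF", evidence, "", "P",
        "", "", "protein", "taxon:9606", "20260101", "DB", sep = "\t")
}

test_that("GAF parsing keeps duplicate-evidence records and drops NOT rows", {
  st <- load_gaf(c("!gaf-version: 2.2",
                   gaf_line("p1", "GO:0000003", "EXP"),
                   gaf_line("p1", "GO:0000003", "IEA"),
                   gaf_line("p2", "GO:0000004", "IDA", qualifier = "NOT|enables")),
                 text = TRUE)
  expect_equal(nrow(st), 2L)
  expect_setequal(st$evidence, c("EXP", "IEA"))
  empty <- load_gaf("!gaf-version: 2.2", text = TRUE)
  expect_equal(nrow(empty), 0L)
  expect_error(load_gaf("too\tfew\tcols", text = TRUE), "line 1")
})

test_that("strict NOSEQ filtering removes every term sequence evidence touched", {
  st <- annotation_store(c("p", "p", "p", "q"),
                         c("g1", "g1", "g2", "g3"),
                         c("EXP", "ISS", "IEA", "IPI"),
                         "S1")
  strict <- filter_noseq(st, mode = "strict")
  expect_equal(nrow(strict), 1L)  # only (q, g3, IPI) survives
  expect_equal(strict$protein, "q")
  record <- filter_noseq(st, mode = "record")
  expect_setequal(paste(record$protein, record$term),
                  c("p g1", "q g3"))  # (p,g1,EXP) kept in record mode
  # containment: strict subset of record subset of input
  key <- function(x) paste(x$protein, x$term, x$evidence)
  expect_true(all(key(strict) %in% key(record)))
  expect_true(all(key(record) %in% key(st)))
})

test_that("propagation follows the true-path rule and is idempotent", {
  dag <- toy_dag()
  st <- annotation_store("p", "GO:0000003", "EXP", "S1")
  pg <- propagate(st, dag)
  expect_setequal(pg$term, c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_true(all(pg$evidence == "EXP"))
  expect_identical(as.data.frame(propagate(pg, dag)), as.data.frame(pg))
  root_only <- propagate(annotation_store("p", "GO:0000001", "EXP", "S1"), dag)
  expect_equal(nrow(root_only), 1L)
  expect_warning(propagate(annotation_store("p", "GO:0444444", "EXP", "S1"),
                           dag), "absent")
})

test_that("information content matches the closed form and is antitone", {
  dag <- toy_dag()
  st <- annotation_store(c("p1", "p2", "p3", "p4", "p1", "p2"),
                         c("GO:0000001", "GO:0000001", "GO:0000001",
                           "GO:0000001", "GO:0000003", "GO:0000003"),
                         "EXP", "S1")
  ic <- information_content(propagate(st, dag), dag)
  expect_equal(unname(ic["GO:0000001"]), 0)
  expect_equal(unname(ic["GO:0000003"]), log(2))  # 2 of 4 proteins
  all_st <- annotation_store(paste0("p", 1:4), "GO:0000002", "EXP", "S1")
  ic2 <- information_content(propagate(all_st, dag), dag)
  expect_equal(unname(ic2["GO:0000002"]), 0)
  # antitone along is_a after propagation
  mix <- annotation_store(c("p1", "p2", "p3", "p4"),
                          c("GO:0000003", "GO:0000003", "GO:0000004",
                            "GO:0000002"), "EXP", "S1")
  ic3 <- information_content(propagate(mix, dag), dag)
  expect_gte(ic3["GO:0000003"], ic3["GO:0000002"])
  expect_gte(ic3["GO:0000002"], ic3["GO:0000001"])
  expect_error(information_content(propagate(annotation_store(
    character(0), character(0), character(0), character(0)), dag), dag),
    "empty")
})

test_that("max-variant Resnik uses the most informative common ancestor", {
  dag <- toy_dag()
  # 4 root proteins; term GO:0000003 annotates exactly one of them
  st <- annotation_store(c("p1", "p2", "p3", "p4", "p1", "p2"),
                         c("GO:0000003", "GO:0000004", "GO:0000001",
                           "GO:0000001", "GO:0000002", "GO:0000002"),
                         "EXP", "S1")
  corpus <- propagate(st, dag)
  ic <- information_content(corpus, dag)
  # p1 and p2 share GO:0000002 (their specific terms differ)
  expect_equal(resnik_max("p1", "p2", corpus, dag, ic),
               unname(ic["GO:0000002"]))
  # sharing only the root scores 0
  expect_equal(resnik_max("p1", "p3", corpus, dag, ic), 0)
  # self-similarity is the max IC over own terms
  expect_equal(resnik_max("p1", "p1", corpus, dag, ic),
               max(ic[corpus$term[corpus$protein == "p1"]]))
  # symmetry
  expect_equal(resnik_max("p1", "p2", corpus, dag, ic),
               resnik_max("p2", "p1", corpus, dag, ic))
  # unannotated protein: no score, not zero
  expect_true(is.na(resnik_max("p1", "missing", corpus, dag, ic)))
  # both annotated with a term of IC log(4) scores log(4)
  st2 <- annotation_store(c("a", "b", paste0("f", 1:4)),
                          c("GO:0000003", "GO:0000003",
                            rep("GO:0000001", 4)), "EXP", "S1")
  corpus2 <- propagate(st2, dag)
  ic2 <- information_content(corpus2, dag)
  expect_equal(unname(ic2["GO:0000003"]), log(3))  # 2 of 6
  expect_equal(resnik_max("a", "b", corpus2, dag, ic2), log(3))
})

test_that("adding a shared specific term never lowers Resnik", {
  dag <- toy_dag()
  base <- annotation_store(c("a", "b", "c", "d"),
                           c("GO:0000002", "GO:0000002", "GO:0000001",
                             "GO:0000001"), "EXP", "S1")
  plus <- annotation_store(c("a", "b", "c", "d", "a", "b"),
                           c("GO:0000002", "GO:0000002", "GO:0000001",
                             "GO:0000001", "GO:0000003", "GO:0000003"),
                           "EXP", "S1")
  c1 <- propagate(base, dag)
  c2 <- propagate(plus, dag)
  r1 <- resnik_max("a", "b", c1, dag)
  r2 <- resnik_max("a", "b", c2, dag)
  expect_gte(r2, r1)
})

test_that("(S, M) well-annotation counts specific direct terms", {
  st <- annotation_store(c("p", "p", "q", "q", "q", "q", "q", "r"),
                         c("t1", "t2", "t3", "t3", "t3", "t3", "t3", "t3"),
                         "EXP",
                         c("S1", "S1", rep("S1", 5), "S1"))
  # t1, t2 annotate only p; t3 annotates q and r (2 proteins)
  expect_true(well_annotated("p", st, S = 2, M = 1))
  expect_false(well_annotated("p", st, S = 3, M = 1))
  expect_false(well_annotated("q", st, S = 1, M = 1))
  expect_true(well_annotated("q", st, S = 1, M = 2))
  # a term above the M cap never counts
  big <- annotation_store(c(paste0("x", 1:5), "y"),
                          c(rep("tt", 5), "tt"), "EXP", "S1")
  expect_false(well_annotated("y", big, S = 1, M = 4))
})
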