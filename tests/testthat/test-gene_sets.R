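test_that("disjointness enforcement removes exactly the shared genes", {
  r <- enforce_disjoint(c("a", "b", "c"), c("c", "d"))
  expect_setequal(r$a, c("a", "b")); expect_setequal(r$b, "d")
  expect_identical(r$shared, "c")

  r2 <- enforce_disjoint("x", "x")
  expect_length(r2$a, 0); expect_length(r2$b, 0)

  r3 <- enforce_disjoint(c("a", "b"), c("c", "d"))
  expect_setequal(r3$a, c("a", "b")); expect_setequal(r3$b, c("c", "d"))

  # never grows either set; preserves genes outside the intersection
  set.seed(1)
  for (i in 1:20) {
    A <- sample(letters, sample(5:15, 1)); B <- sample(letters, sample(5:15, 1))
    r <- enforce_disjoint(A, B)
    expect_lte(length(r$a), length(unique(A)))
    expect_lte(length(r$b), length(unique(B)))
    expect_setequal(r$a, setdiff(A, B))
    expect_setequal(r$b, setdiff(B, A))
    expect_length(intersect(r$a, r$b), 0)
  }
})

test_that("gene sets must live inside the background", {
  expect_error(gene_set_collection(list(S = c("a", "zz")), background = c("a", "b")), "zz")
  gsc <- gene_set_collection(list(S = c("a", "a", "b")), background = c("a", "b", "c"))
  expect_setequal(gsc$S, c("a", "b"))
})

test_that("annotation propagation follows is_a ancestry, de-duplicates diamonds, detects cycles", {
  ont <- ontology(c("t0", "t1"), parents = list(t1 = "t0"))
  annot <- annotation_table(c("g"), data.frame(gene = "g", category = "t1"))
  # add the parent as an (empty) category so it appears in the table
  inc <- cbind(annot$incidence, t0 = FALSE)
  annot <- annotation_table("g", inc)
  out <- propagate_annotations(annot, ont)
  expect_true(out$incidence["g", "t0"] && out$incidence["g", "t1"])

  # diamond: t1 is_a {t0a, t0b}, both is_a troot; one gene, one mark per term
  ont2 <- ontology(c("troot", "t0a", "t0b", "t1"),
                   parents = list(t1 = c("t0a", "t0b"), t0a = "troot", t0b = "troot"))
  inc2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1,
                 dimnames = list("g", c("t1", "t0a", "t0b", "troot")))
  out2 <- propagate_annotations(annotation_table("g", inc2), ont2)
  expect_true(all(out2$incidence["g", ]))
  expect_true(is.logical(out2$incidence))   # membership, not a path count

  ont3 <- ontology(c("a", "b"), parents = list(a = "b", b = "a"))
  expect_error(propagate_annotations(annotation_table("g", inc2[, 1:2, drop = FALSE]),
                                     ont3), "cycle")
})

test_that("propagation is idempotent and category counts never decrease", {
  set.seed(42)
  terms <- paste0("t", 1:8)
  parents <- list(t2 = "t1", t3 = "t1", t4 = c("t2", "t3"), t5 = "t4",
                  t6 = "t1", t7 = c("t5", "t6"))
  ont <- ontology(terms, parents)
  genes <- paste0("g", 1:10)
  long <- data.frame(gene = sample(genes, 25, replace = TRUE),
                     category = sample(terms, 25, replace = TRUE))
  long <- unique(long)
  annot <- annotation_table(genes, long)
  once <- propagate_annotations(annot, ont)
  twice <- propagate_annotations(once, ont)
  expect_identical(once$incidence, twice$incidence)
  expect_true(all(colSums(once$incidence) >= colSums(annot$incidence)[colnames(once$incidence)]))
})

test_that("OBO reader captures terms, names and is_a links", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:1", "name: root", "",
           "[Term]", "id: GO:2", "name: child", "is_a: GO:1 ! root", "",
           "[Term]", "id: GO:3", "name: gone", "is_obsolete: true", "",
           "[Typedef]", "id: part_of")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, path)
  ont <- read_obo(path)
  expect_setequal(ont$terms, c("GO:1", "GO:2"))
  expect_identical(ont$parents$`GO:2`, "GO:1")
  expect_identical(unname(ont$term_names["GO:2"]), "child")
  expect_setequal(term_ancestors(ont, "GO:2"), "GO:1")
})

test_that("GMT files round-trip", {
  sets <- list(IS = c("a", "b", "c"), NS = c("d", "e"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back[order(names(back))], sets[order(names(sets))])
})

test_that("bundled TNF-alpha annotation table matches its printed category counts", {
  a <- load_tnf_is_annotations()
  expect_length(a$background, 31)
  counts <- colSums(a$incidence)
  expect_equal(unname(counts["GO:0002376"]), 22)  # immune system process
  expect_equal(unname(counts["GO:0006955"]), 22)  # immune response
  expect_equal(unname(counts["GO:0050900"]), 9)   # leukocyte migration
  expect_equal(unname(counts["GO:0002682"]), 19)  # regulation of IS process
  expect_equal(unname(counts["GO:0002684"]), 13)  # positive regulation
  expect_equal(unname(counts["GO:0002253"]), 6)   # activation of immune response
  # Ccl5 carries five categories: all but activation of immune response
  ccl5 <- a$incidence["ENSRNOG00000010906", ]
  expect_equal(sum(ccl5), 5)
  expect_false(ccl5[["GO:0002253"]])
})
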