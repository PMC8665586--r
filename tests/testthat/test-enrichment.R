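test_that("GMT files round-trip through the collection type", {
  sets <- gene_set_collection(
    list(term1 = c("a", "b", "c"), term2 = c("b", "d")),
    description = c(term1 = "first", term2 = "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back$term1, c("a", "b", "c"))
  expect_identical(unname(attr(back, "description")["term2"]), "second")
  expect_error(gene_set_collection(list(a = character(0))), "non-empty")
  expect_error(gene_set_collection(list(c("x"))), "named")
})

test_that("hypergeometric ORA matches hand-summed and enumerated tails", {
  universe <- sprintf("g%02d", 1:20)
  coll <- gene_set_collection(list(hit = universe[1:5]))
  res <- ora(universe[c(1:4, 10)], coll, universe)   # k=4 of K=5, n=5
  # exact: [C(5,4)C(15,1) + C(5,5)C(15,0)] / C(20,5) = 76/15504
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 4); expect_equal(res$K, 5); expect_equal(res$N, 20)

  # brute-force enumeration oracle on small universes
  set.seed(3)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    uni <- sprintf("u%02d", seq_len(N))
    set <- sample(uni, sample(2:(N - 2), 1))
    n <- sample(2:(N - 2), 1)
    query <- sample(uni, n)
    k <- length(intersect(query, set))
    res <- ora(query, gene_set_collection(list(s = set)), uni)
    expect_equal(res$p, enumerated_ora_p(set, uni, n, k), tolerance = 1e-10)
  }
})

test_that("ORA boundary behaviour is sound", {
  universe <- letters[1:10]
  coll <- gene_set_collection(list(all = universe, some = letters[1:4]))
  res <- ora(universe, coll, universe)   # query = universe
  expect_true(all(res$p == 1))
  expect_true(all(res$k == res$K))
  # disjoint term
  res2 <- ora(letters[5:7], gene_set_collection(list(s = letters[1:4])),
              universe)
  expect_equal(res2$k, 0)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  expect_warning(r0 <- ora(character(0), coll, universe), "empty query")
  expect_equal(nrow(r0), 0)
  expect_error(ora("zz", coll, universe), "subset of the universe")
})

test_that("ORA p is monotone in the overlap count", {
  p_at <- function(k) {
    uni <- sprintf("g%02d", 1:30)
    coll <- gene_set_collection(list(s = uni[1:10]))
    query <- c(uni[seq_len(k)], uni[11:(11 + 8 - k - 1)])  # size 8, k hits
    ora(query, coll, uni)$p
  }
  ps <- vapply(1:6, p_at, numeric(1))
  expect_true(all(diff(ps) < 0))  # more overlap -> smaller p
})

test_that("the Jaccard term network has the advertised edges and weights", {
  res <- structure(
    data.frame(term = c("t1", "t2", "t3"),
               adj_p = c(1e-4, 1e-3, 1e-2)),
    class = c("enrichment_result", "data.frame"))
  res$overlap <- list(c("A", "B", "C"), c("A", "B", "C"), c("D"))
  # pairwise Jaccards: (t1,t2)=1, (t1,t3)=0, (t2,t3)=0
  net <- term_network(res, min_jaccard = 0.4)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$jaccard, 1)
  expect_equal(net$nodes$weight, -log10(c(1e-4, 1e-3, 1e-2)))
  # classic {A,B,C} vs {B,C,D} example
  res$overlap <- list(c("A", "B", "C"), c("B", "C", "D"), c("X"))
  net2 <- term_network(res, min_jaccard = 0)
  e <- net2$edges
  expect_equal(e$jaccard[e$term_a == "t1" & e$term_b == "t2"], 0.5)
  # pairwise Jaccards (1, 1/4, 1/4): the 0.4 cut-off keeps one edge,
  # a 0.2 cut-off keeps all three
  res$overlap <- list(c("A", "B"), c("A", "B"), c("A", "X", "Y"))
  net3 <- term_network(res, min_jaccard = 0.4)
  expect_equal(nrow(net3$edges), 1)
  expect_equal(nrow(term_network(res, min_jaccard = 0.2)$edges), 3)
})

test_that("planted-term recovery works end to end", {
  sim <- generate_proteomics(label_frame(), seed = 17)
  filt <- detectability_filter(sim$matrix)
  grp <- factor(ifelse(sim$labels == 1, "pos", "neg"), c("neg", "pos"))
  de <- moderated_t(filt, grp)
  enr <- ora(de$peptide_id[de$dep], sim$gmt, rownames(filt))
  expect_identical(enr$term[1], "PLANTED_SET")
  expect_lt(enr$adj_p[1], 0.05)
})
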