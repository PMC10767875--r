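test_that("simRel collapses to 1 - p on identical terms and 0 at the root", {
  fx <- fixture_dag()
  expect_equal(simrel("GO:0000105", "GO:0000105", fx$stats, fx$ontology),
               1 - 0.05)
  # t3 and t2 share only the root
  expect_equal(simrel("GO:0000103", "GO:0000102", fx$stats, fx$ontology), 0)
  expect_error(simrel("GO:0000101", "GO:0000006", fx$stats,
                      parse_ontology(fixture_obo())), "namespace")
})

test_that("simRel equals the exhaustive common-ancestor maximum on the DAG", {
  fx <- fixture_dag()
  terms <- fx$stats$term_id
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      got <- simrel(terms[i], terms[j], fx$stats, fx$ontology)
      want <- simrel_oracle(terms[i], terms[j], fx$stats, fx$ontology)
      expect_equal(got, want, tolerance = 1e-12,
                   label = paste(terms[i], terms[j]))
      expect_gte(got, 0); expect_lte(got, 1)
    }
  }
  # symmetry
  S <- simrel_matrix(terms, fx$stats, fx$ontology)
  expect_equal(S, t(S))
})

test_that("classical MDS reproduces simple configurations", {
  # two points at distance 0.8
  S <- matrix(c(1, 0.2, 0.2, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  xy <- mds_embed(S)
  expect_equal(as.numeric(stats::dist(xy)), 0.8, tolerance = 1e-12)
  # three mutually unrelated terms: an equilateral triangle of side 1
  S3 <- diag(3); dimnames(S3) <- list(letters[1:3], letters[1:3])
  d <- stats::dist(mds_embed(S3))
  expect_equal(as.numeric(d), rep(1, 3), tolerance = 1e-9)
  # duplicated rows embed at (numerically) identical coordinates
  S4 <- matrix(c(1, 1, 0.3, 1, 1, 0.3, 0.3, 0.3, 1), 3, 3)
  xy4 <- mds_embed(S4)
  expect_lt(max(abs(xy4[1, ] - xy4[2, ])), 1e-6)
  # single point: degenerate map at the origin
  single <- mds_embed(matrix(1, 1, 1, dimnames = list("a", "a")))
  expect_true(attr(single, "degenerate"))
  expect_equal(unname(single[1, ]), c(0, 0))
  expect_error(mds_embed(matrix(c(1, 0.5, 0.1, 1), 2, 2)), "symmetric")
})

test_that("the embedding is deterministic, bit for bit", {
  fx <- fixture_dag()
  S <- simrel_matrix(fx$stats$term_id, fx$stats, fx$ontology)
  expect_identical(mds_embed(S), mds_embed(S))
})

test_that("export_map emits one map per namespace with significant terms", {
  fx <- fixture_dag()
  rows <- data.frame(
    term_id = c("GO:0000103", "GO:0000104", "GO:0000105"),
    name = c("t3", "t4", "t5"), namespace = "BP",
    p_uncorrected = c(1e-5, 1e-4, 0.2),
    p_bonferroni = c(3e-5, 3e-4, 0.6),
    p_bh = c(3e-5, 1.5e-4, 0.2),
    stringsAsFactors = FALSE)
  maps <- export_map(rows, fx$stats, fx$ontology, alpha = 0.05, method = "bh")
  expect_named(maps, "BP")  # no MF or CC map: "up to three"
  expect_equal(nrow(maps$BP), 2)  # t5 not significant
  expect_equal(maps$BP$information_content,
               unname(-log(c(0.2, 0.1))), tolerance = 1e-12)
  # a single significant term sits at the origin
  maps1 <- export_map(rows[1, ], fx$stats, fx$ontology,
                      alpha = 0.05, method = "bh")
  expect_equal(c(maps1$BP$x, maps1$BP$y), c(0, 0))
  # JSON + PNG writers produce one pair per namespace
  dir <- withr::local_tempdir()
  paths <- write_semantic_maps(maps, dir)
  expect_setequal(basename(paths), c("BP.json", "BP.png"))
  js <- jsonlite::fromJSON(file.path(dir, "BP.json"))
  expect_equal(js$term, maps$BP$term_id)
})

test_that("embedded distances track semantic dissimilarity on clustered maps", {
  # enriched GO sets typically split into a few semantic themes; the map
  # is expected to preserve dissimilarity ranks for such clustered sets
  # (an arbitrary scattered term set has no faithful 2-D representation)
  make_clustered <- function(seed, sizes = c(10, 10)) {
    set.seed(seed)
    lines <- c("format-version: 1.2", "",
               "[Term]", "id: GO:1000000", "name: biological_process",
               "namespace: biological_process", "")
    k <- 0
    terms <- character(0)
    probs <- c("GO:1000000" = 1)
    for (cl in seq_along(sizes)) {
      parent <- "GO:1000000"
      p <- stats::runif(1, 0.3, 0.5)
      for (i in seq_len(sizes[cl])) {
        k <- k + 1
        id <- sprintf("GO:1%06d", k)
        lines <- c(lines, "[Term]", paste0("id: ", id),
                   paste0("name: c", cl, "t", i),
                   "namespace: biological_process",
                   paste0("is_a: ", parent), "")
        p <- p * stats::runif(1, 0.5, 0.9)
        probs[id] <- p
        terms <- c(terms, id)
        parent <- id
      }
    }
    onto <- parse_ontology(paste(lines, collapse = "\n"))
    st <- data.frame(term_id = names(probs), namespace = "BP", count = 1L,
                     probability = unname(probs), ic = -log(unname(probs)),
                     stringsAsFactors = FALSE)
    rownames(st) <- st$term_id
    class(st) <- c("term_stats", "data.frame")
    list(onto = onto, stats = st, terms = terms)
  }
  for (seed in 1:3) {
    w <- make_clustered(seed)
    S <- simrel_matrix(w$terms, w$stats, w$onto)
    xy <- mds_embed(S)
    diss <- as.numeric(stats::as.dist(1 - S))
    emb <- as.numeric(stats::dist(xy))
    rho <- stats::cor(diss, emb, method = "spearman")
    expect_gte(rho, 0.8)
  }
})
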