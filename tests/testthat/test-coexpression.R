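make_dataset <- function(m, id = "d1", logged = TRUE) {
  expression_dataset(id, m, logged = logged)
}

test_that("log2 transform is exact and respects the already-logged flag", {
  m <- matrix(c(0, 3, 1, 7), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  d <- log2_transform(make_dataset(m, logged = FALSE))
  expect_equal(unname(d$matrix["g1", 1]), 0)  # log2(0 + 1)
  expect_equal(unname(d$matrix["g2", 1]), 2)  # log2(3 + 1)
  expect_equal(unname(d$matrix["g2", 2]), 3)  # log2(7 + 1)
  expect_true(d$logged)
  already <- make_dataset(m - 5, logged = TRUE)
  expect_identical(log2_transform(already), already)
  expect_error(log2_transform(make_dataset(m - 5, logged = FALSE)),
               "negative")
})

test_that("Pearson matrices match hand-computed values and flag zero variance", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1), g3 = c(1, 2, 4),
             g4 = c(1, 3, 5), g5 = c(2, 2, 2))
  r <- pearson_matrix(make_dataset(m))
  expect_equal(r["g1", "g1"], 1)
  expect_equal(r["g1", "g2"], -1)
  # hand evaluation of Pearson on (1,2,4) vs (1,3,5):
  # cov = 6, var terms 42/9 and 8 -> r = 6/sqrt(112/3)
  expect_equal(r["g3", "g4"], 6 / sqrt(112 / 3), tolerance = 1e-12)
  expect_true(all(is.na(r["g5", ])))
  expect_equal(attr(r, "excluded"), "g5")
})

test_that("meta-combination reproduces the hand-computed Fisher-z average", {
  # datasets (r = 0.5, n = 10) and (r = 0.8, n = 20):
  # zbar = (7*atanh(0.5) + 17*atanh(0.8)) / 24 ; tanh(zbar) = 0.7345
  r1 <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  r2 <- matrix(c(1, 0.8, 0.8, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  meta <- meta_combine(list(r1, r2), c(10, 20))
  expect_equal(meta$r["a", "b"], 0.7345, tolerance = 5e-5)
  expect_equal(meta$coverage["a", "b"], 2L)

  # single dataset: meta-PCC equals the plain Pearson value
  one <- meta_combine(list(r1), 10)
  expect_equal(one$r["a", "b"], 0.5, tolerance = 1e-9)
  # r = 1 everywhere: fixed point within clamp tolerance
  r3 <- matrix(1, 2, 2, dimnames = dimnames(r1))
  fix <- meta_combine(list(r3, r3), c(10, 20))
  expect_equal(fix$r["a", "b"], 1, tolerance = 1e-5)
  expect_error(meta_combine(list(r1), 3), "n <= 3")
})

test_that("meta-combination is symmetric, order-invariant, and a fixed point at equal r", {
  withr::with_seed(4, {
    g <- paste0("g", 1:6)
    mats <- lapply(1:3, function(i) {
      m <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(g, NULL))
      pearson_matrix(make_dataset(m, id = paste0("d", i)))
    })
  })
  ns <- c(8, 12, 20)
  meta <- meta_combine(mats, ns)
  expect_equal(meta$r, t(meta$r))
  perm <- c(3, 1, 2)
  meta2 <- meta_combine(mats[perm], ns[perm])
  expect_equal(meta$r, meta2$r)
  # equal r across equal-n datasets is returned exactly
  req <- mats[[1]]
  same <- meta_combine(list(req, req), c(9, 9))
  expect_equal(same$r["g1", "g2"], req["g1", "g2"], tolerance = 1e-9)
  # pairs with no coverage are missing
  ra <- matrix(c(1, .2, .2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  rb <- matrix(c(1, .4, .4, 1), 2, 2, dimnames = list(c("c", "d"), c("c", "d")))
  part <- meta_combine(list(ra, rb), c(10, 10))
  expect_true(is.na(part$r["a", "c"]))
  expect_equal(part$coverage["a", "c"], 0L)
})

test_that("KNN scores match a hand-worked toy case at K = 0.25% of 2000", {
  # 10 candidate genes with known correlations and labels; training
  # size chosen so K = 0.25% of 2000 -> k = 5
  genes <- sprintf("t%02d", 1:10)
  rvals <- seq(0.95, 0.05, length.out = 10)
  labels <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  G <- c("q", genes)
  r <- diag(length(G))
  dimnames(r) <- list(G, G)
  r["q", genes] <- rvals
  r[genes, "q"] <- rvals
  meta <- structure(list(genes = G, r = r,
                         coverage = matrix(1L, length(G), length(G),
                                           dimnames = list(G, G))),
                    class = "meta_pcc")
  # pad the training roster to 2000 with genes absent from meta (they
  # rank last and never enter the top 5)
  pad <- sprintf("z%04d", 1:1990)
  cfg <- knn_config(c(genes, pad), c(labels, rep(FALSE, 1990)),
                    k_percent = 0.25)
  s <- knn_scores("q", meta, cfg)
  expect_equal(unname(s), mean(labels[1:5]))  # top-5: +,-,+,+,- = 0.6
  expect_equal(unname(s), 0.6)
})

test_that("KNN scores agree with a full-sort brute-force oracle on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      g <- sprintf("g%02d", 1:50)
      m <- matrix(rnorm(50 * 12), 50, 12, dimnames = list(g, NULL))
      lab <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(.4, .6))
    })
    meta <- meta_combine(list(pearson_matrix(make_dataset(m))), 12)
    train <- g[1:40]
    tlab <- lab[1:40]
    cfg <- knn_config(train, tlab)
    query <- g[45]
    s <- knn_scores(query, meta, cfg)
    # oracle: explicit full sort, ties by gene id
    rv <- meta$r[query, train]
    ord <- order(-rv, train)
    for (i in seq_along(cfg$k_percent)) {
      k <- max(1, floor(cfg$k_percent[i] / 100 * 40 + 0.5))
      expect_equal(unname(s[i]), mean(tlab[ord][1:k]))
    }
    # monotonicity: flipping a top-k neighbour to positive never lowers a score
    k1 <- max(1, floor(cfg$k_percent[5] / 100 * 40 + 0.5))
    top <- ord[1:k1]
    flip <- tlab; flip[top[1]] <- TRUE
    s2 <- knn_scores(query, meta, knn_config(train, flip))
    expect_true(all(s2 >= s - 1e-12))
  }
})

test_that("training queries never count themselves and saturation yields all ones", {
  g <- c("a", "b", "c", "d")
  r <- matrix(0.9, 4, 4, dimnames = list(g, g)); diag(r) <- 1
  meta <- meta_combine(list(r), 10)
  cfg <- knn_config(g, c(TRUE, TRUE, TRUE, TRUE), k_percent = c(25, 50))
  s <- knn_scores("a", meta, cfg)
  expect_equal(unname(s), c(1, 1))
  # all-positive neighbours at every K saturate at 1
  cfg2 <- knn_config(g, c(FALSE, TRUE, TRUE, TRUE), k_percent = c(25, 50, 75))
  s2 <- knn_scores("a", meta, cfg2)  # query a excluded from its own ranking
  expect_equal(unname(s2), c(1, 1, 1))
  expect_error(knn_scores("missing", meta, cfg), "not in meta-PCC")
  expect_error(knn_config(character(0), logical(0)), "empty training")
})

test_that("reference mapping attaches gene ids, leaves unmapped absent, rejects conflicts", {
  rec <- toy_records(c("MKVLA", "MKWWA", "MKYYA"), ids = c("p1", "p2", "p3"))
  map <- data.frame(protein_id = c("p1", "p3"), gene_id = c("g1", "g3"))
  out <- map_to_reference(rec, map)
  expect_equal(out$gene_id, c("g1", NA, "g3"))
  # unmapped protein -> five-zero co-expression block downstream
  meta <- meta_combine(list(matrix(1, 1, 1, dimnames = list("g1", "g1"))), 10)
  cfg <- knn_config(c("g1", "g3"), c(TRUE, FALSE))
  tab <- knn_score_table(out, meta, cfg)
  expect_true(all(tab["p2", ] == 0))
  bad <- rbind(map, data.frame(protein_id = "p1", gene_id = "gX"))
  expect_error(map_to_reference(rec, bad), "conflicting")
  # exact duplicates are tolerated
  dupok <- rbind(map, map[1, ])
  expect_silent(map_to_reference(rec, dupok))
})

test_that("expression manifests round-trip through the text interface", {
  dir <- tempfile(); dir.create(dir)
  withr::with_seed(8, m <- matrix(abs(rnorm(12)), 3, 4,
                                  dimnames = list(paste0("g", 1:3),
                                                  paste0("S", 1:4))))
  write.table(data.frame(gene = rownames(m), m), file.path(dir, "d1.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(dataset_id = "d1", path = "d1.tsv",
                         n_samples = 4, logged = FALSE),
              file.path(dir, "expression_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ds <- read_expression_manifest(file.path(dir, "expression_manifest.tsv"))
  expect_length(ds, 1)
  expect_true(ds[[1]]$logged)  # transformed on load
  expect_equal(ds[[1]]$matrix, log2(m + 1))
})
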