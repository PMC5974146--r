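alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("amino-acid frequencies are exact on hand-tallied windows", {
  f <- aa_frequency(strrep("A", 22), 22)
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)

  # 22-residue window: the full alphabet plus a second A and C
  f2 <- aa_frequency("ACDEFGHIKLMNPQRSTVWYAC", 22)
  expect_equal(unname(f2["A"]), 2 / 22)
  expect_equal(unname(f2["C"]), 2 / 22)
  expect_equal(unname(f2["W"]), 1 / 22)
  expect_equal(sum(f2), 1)
})

test_that("frequency denominator excludes ambiguity codes and handles short sequences", {
  # X excluded: 10 standard residues in a 11-char window
  f <- aa_frequency("AAAAAXCCCCC", 22)
  expect_equal(unname(f["A"]), 5 / 10)
  expect_equal(sum(f), 1)
  # window longer than sequence = whole sequence
  expect_equal(aa_frequency("MKV", 22), aa_frequency("MKV", Inf))
  expect_error(aa_frequency("XXX", 22), "no standard residues")
})

test_that("frequency output sums to one and is alphabet-equivariant (property)", {
  for (seed in 1:20) {
    s <- random_aa(1, seed = seed)
    f <- aa_frequency(s, 22)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    # permutation equivariance: frequencies are independent per residue
    perm <- withr::with_seed(seed, sample(20))
    expect_equal(unname(f[perm]),
                 unname(vapply(alphabet[perm], function(a)
                   f[[a]], numeric(1))))
  }
})

test_that("ASCII PSSM parsing recovers hand-read values and remaps columns", {
  seqs <- "MKC"
  mat <- matrix(0L, 3, 20, dimnames = list(NULL, alphabet))
  mat[1, "M"] <- 8L; mat[1, "A"] <- -2L
  mat[2, "K"] <- 5L; mat[2, "D"] <- -4L
  mat[3, "C"] <- 9L; mat[3, "W"] <- -3L
  prof <- profile_matrix("toy", mat)
  path <- tempfile(fileext = ".pssm")
  write_pssm(prof, seqs, path)
  got <- parse_pssm(path, seqs, "toy")
  expect_equal(unname(got$mat), unname(mat))
  expect_false(got$scaled)
  expect_equal(got$source, "psiblast_ascii")
  # single-position file
  write_pssm(profile_matrix("p1", mat[1, , drop = FALSE]), "M", path)
  one <- parse_pssm(path, "M")
  expect_equal(nrow(one$mat), 1L)
  expect_equal(unname(one$mat[1, "M"]), 8)
  # residue column disagreement
  expect_error(parse_pssm(path, "K"), "disagrees with sequence")
  # length mismatch
  expect_error(parse_pssm(path, "MK"), "rows but sequence")
})

test_that("profile scaling maps min/max to -1/1, constants to zero, and is monotone", {
  m <- matrix(c(-8, 0, 8, 4), 1, 4)
  m <- cbind(m, matrix(0, 1, 16))
  p <- scale_profile(profile_matrix("a", m))
  expect_equal(p$mat[1, 1:3], setNames(c(-1, 0, 1), alphabet[1:3]))
  expect_true(p$scaled)
  expect_error(scale_profile(p), "already scaled")

  # min -3, max 5: entry 1 -> 2*(1+3)/8 - 1 = 0
  m2 <- matrix(c(-3, 5, 1, rep(0, 17)), 1, 20)
  p2 <- scale_profile(profile_matrix("b", m2))
  expect_equal(unname(p2$mat[1, 3]), 0)

  const <- scale_profile(profile_matrix("c", matrix(7, 4, 20)))
  expect_true(all(const$mat == 0))

  # monotone + idempotent in effect
  r <- matrix(rnorm(200), 10, 20)
  sp <- scale_profile(profile_matrix("d", r))
  expect_equal(order(r), order(sp$mat))
  again <- scale_profile(profile_matrix("d", sp$mat))
  expect_equal(again$mat, sp$mat)
})

test_that("substitution fallback repeats BLOSUM rows and zeroes ambiguity codes", {
  p <- substitution_fallback_profile("AA")
  expect_equal(p$mat[1, ], p$mat[2, ])
  expect_equal(p$source, "substitution_fallback")
  px <- substitution_fallback_profile("AXC")
  expect_true(all(px$mat[2, ] == 0))
  expect_false(all(px$mat[1, ] == 0))
  for (s in c("MKV", "ACDEFGHIKLMNPQRSTVWY"))
    expect_equal(nrow(substitution_fallback_profile(s)$mat), nchar(s))
})

test_that("N-terminal profile features flatten position-major with zero padding", {
  m <- matrix(0, 10, 20)
  m[2, 3] <- 1  # position 2, third alphabet letter
  p <- profile_matrix("a", m, scaled = TRUE)
  v <- nterm_profile_feature(p, 22)
  expect_length(v, 440)
  expect_equal(v[23], 1)            # (2-1)*20 + 3
  expect_true(all(v[201:440] == 0)) # positions 11-22 padded
  expect_error(nterm_profile_feature(p, 4), "\\[5, 50\\]")
  expect_error(nterm_profile_feature(profile_matrix("u", m), 22), "scaled")
})

test_that("global profile features average rows by residue type", {
  m <- matrix(runif(80, -1, 1), 4, 20)
  p <- profile_matrix("a", m, scaled = TRUE)
  v <- global_profile_feature(p, "AAAA")
  expect_length(v, 400)
  expect_equal(v[1:20], unname(colMeans(m)))
  expect_true(all(v[21:400] == 0))

  v2 <- global_profile_feature(profile_matrix("b", m[1:2, ], scaled = TRUE),
                               "AC")
  expect_equal(v2[1:20], unname(m[1, ]))
  expect_equal(v2[21:40], unname(m[2, ]))

  # identical rows: present types echo the row, absent types zero
  row <- runif(20, -1, 1)
  mm <- matrix(rep(row, 3), 3, 20, byrow = TRUE)
  v3 <- global_profile_feature(profile_matrix("c", mm, scaled = TRUE),
                               "ACA")
  expect_equal(v3[1:20], row)    # A present
  expect_equal(v3[21:40], row)   # C present
  expect_true(all(v3[41:400] == 0))
})

test_that("feature assembly uses the fixed block order, layout and fallbacks", {
  rec <- toy_records(random_aa(1, seed = 3))[1, ]
  prof <- substitution_fallback_profile(rec$sequence, rec$id)
  fv <- assemble_features(rec, prof, knn = NULL)
  expect_length(fv$values, 865)
  expect_equal(fv$layout$block, c("AAFreq.NT", "PSSM.NT", "PSSM", "Coexpr"))
  expect_equal(fv$layout$length, c(20L, 440L, 400L, 5L))
  expect_equal(fv$layout$offset, c(0L, 20L, 460L, 860L))
  # unmapped protein: Coexpr block is five zeros
  expect_true(all(fv$values[861:865] == 0))

  only <- assemble_features(rec, config = feature_config(blocks = "AAFreq.NT"))
  expect_length(only$values, 20)

  expect_error(assemble_features(rec, profile = NULL,
                                 config = feature_config(blocks = "PSSM")),
               "no profile")
})

test_that("feature matrices round-trip losslessly through the text format", {
  pip <- small_pipeline()
  x <- pip$x[1:8, , drop = FALSE]
  attr(x, "layout") <- attr(pip$x, "layout")
  path <- tempfile(fileext = ".tsv")
  write_features(x, path)
  back <- read_features(path)
  expect_identical(dim(back), dim(x))
  expect_identical(rownames(back), rownames(x))
  expect_identical(attr(back, "layout")$block, attr(x, "layout")$block)
  expect_identical(attr(back, "layout")$offset, attr(x, "layout")$offset)
  expect_true(all(back == x))  # bit-exact round trip
  # layout sum property on the full matrix
  expect_equal(ncol(pip$x), sum(attr(pip$x, "layout")$length))
})

test_that("the parser handles the full-width PSI-BLAST ASCII layout with trailing statistics", {
  txt <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("            ",
           "A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   ",
           "A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V"),
    paste0("    1 M    -2  -2  -3  -4  -2  -1  -3  -3  -2   1   2  -2   8",
           "  -1  -3  -2  -1  -2  -2   0    0   0   0   0   0   0   0   0",
           "   0   4   6   0  85   0   0   0   0   0   0   5  0.95 0.12"),
    paste0("    2 K    -1   3   0  -1  -4   2   1  -2  -1  -3  -3   5  -2",
           "  -4  -1  -1  -1  -4  -2  -3    0  13   0   0   0   6   7   0",
           "   0   0   0  64   0   0   0   0   0   0   0   0  0.62 0.11"),
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1372     0.3179",
    "PSI Gapped           0.0482     0.2670")
  f <- tempfile(fileext = ".pssm")
  writeLines(txt, f)
  p <- parse_pssm(f, "MK", "q")
  expect_equal(nrow(p$mat), 2L)
  expect_equal(unname(p$mat[1, c("M", "A", "D")]), c(8, -2, -4))
  expect_equal(unname(p$mat[2, c("K", "R", "V")]), c(5, 3, -3))
})
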