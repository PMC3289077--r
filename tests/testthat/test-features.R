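# a line structure with CA atoms at chosen x positions
line_structure <- function(xs) {
  res <- lapply(seq_along(xs) - 1L, function(i)
    list(chain = "A", res_id = i, res_name = "ALA", kind = "protein",
         coords = c(xs[i + 1L], 0, 0), atoms = "CA"))
  rna <- list(list(chain = "R", res_id = 0L, res_name = "U", kind = "rna",
                   coords = c(0, 50, 0)))
  make_structure(c(res, rna))
}

test_that("spatial_neighbor_order sorts ascending with seq-index tie-break", {
  s <- line_structure(c(0, 3, 7, 12))
  expect_equal(spatial_neighbor_order(s, 1, 4), c(1, 2, 3, 4))
  # brute-force check from another target
  expect_equal(spatial_neighbor_order(s, 3, 4), c(3, 2, 4, 1))
  # w = 1: self only
  expect_equal(spatial_neighbor_order(s, 2, 1), 2)
  # equidistant neighbours: lower index first
  s2 <- line_structure(c(-3, 0, 3))
  expect_equal(spatial_neighbor_order(s2, 2, 3), c(2, 1, 3))
  # short chain errors unless padding is allowed
  expect_error(spatial_neighbor_order(s2, 1, 5), "short chain")
  expect_equal(length(spatial_neighbor_order(s2, 1, 5, allow_short = TRUE)), 3)
})

test_that("spatial order starts at the target and has no duplicates", {
  set.seed(17)
  for (rep in 1:20) {
    sp <- fixture_spec(n_residues = 20, rna_patch = c(5, 8),
                       seed = rep)
    s <- make_complex(sp)
    target <- sample(20, 1)
    ord <- spatial_neighbor_order(s, target, 10)
    expect_equal(ord[1], target)
    expect_equal(anyDuplicated(ord), 0)
  }
})

test_that("build_spapf concatenates profile rows in window order", {
  set.seed(7)
  p <- profile_matrix(matrix(rnorm(20 * 20), 20, 20))
  ord <- c(5, 2, 9, 1)
  v <- build_spapf(p, ord, 4)
  expect_length(v, 80)
  for (j in seq_along(ord))
    expect_equal(v[(20 * (j - 1) + 1):(20 * j)],
                 unname(p$scores[ord[j], ]))
  # w = 15 emits 300 features; w = 1 is the target's own row
  expect_length(build_spapf(p, 1:15, 15), 300)
  expect_equal(build_spapf(p, 3, 1), unname(p$scores[3, ]))
  # NA (padding) and short windows produce zero tails
  v2 <- build_spapf(p, c(5, NA), 3)
  expect_equal(v2[21:60], rep(0, 40))
  expect_error(build_spapf(p, 99, 1), "missing profile")
})

test_that("build_spawasa weights ASA by exponential distance decay", {
  asa <- c(100, 80, 60)
  d <- c(0, 4, 8)
  v <- build_spawasa(asa, d, 3, d0 = 8)
  expect_length(v, 3)
  expect_equal(v[1], 100)                        # unit weight at distance 0
  expect_equal(v[2], 80 * exp(-0.5))
  expect_equal(v[3], 60 * exp(-1))
  expect_length(build_spawasa(rep(1, 15), rep(1, 15), 15), 15)
  # monotone non-increasing in distance for fixed ASA
  dists <- seq(0, 20, by = 0.5)
  vals <- vapply(dists, function(dd)
    build_spawasa(c(50, 50), c(0, dd), 2)[2], numeric(1))
  expect_true(all(diff(vals) <= 0))
  # d0 = Inf recovers the raw ASA window
  expect_equal(build_spawasa(asa, d, 3, d0 = Inf), asa)
  expect_error(build_spawasa(c(1, NA), c(0, 1), 2), "missing annotation")
})

test_that("build_spasecond returns normalised class frequencies", {
  expect_equal(build_spasecond(rep("H", 6)), c(H = 1, E = 0, C = 0))
  expect_equal(build_spasecond(c("H", "H", "E", "C")),
               c(H = 0.5, E = 0.25, C = 0.25))
  set.seed(3)
  for (rep in 1:20) {
    ss <- sample(c("H", "E", "C"), sample(3:12, 1), TRUE)
    expect_equal(sum(build_spasecond(ss)), 1)
  }
  expect_error(build_spasecond(c("H", "Q")), "outside")
})

test_that("sequence baselines window, pad and reject even widths", {
  set.seed(13)
  p <- profile_matrix(matrix(rnorm(10 * 20), 10, 20))
  expect_length(build_seqprofile(p, 5, 15), 300)
  # left padding at the N-terminus
  v <- build_seqprofile(p, 1, 3)
  expect_equal(v[1:20], rep(0, 20))
  expect_equal(v[21:40], unname(p$scores[1, ]))
  expect_error(build_seqprofile(p, 3, 4), "invalid window")
  # interior window equals direct index arithmetic
  v2 <- build_seqprofile(p, 5, 5)
  expect_equal(v2, as.vector(t(p$scores[3:7, ])))

  asa <- seq(10, 100, by = 10)
  expect_equal(build_seqasa(asa, 4, 1), 40)
  expect_equal(build_seqasa(asa, 1, 5), c(0, 0, 10, 20, 30))
  expect_equal(build_seqasa(asa, 9, 5), c(70, 80, 90, 100, 0))
  expect_error(build_seqasa(asa, 2, 2), "invalid window")
})

test_that("featurize_complex assembles shapes, labels and per-row vectors", {
  sp <- fixture_spec(n_residues = 30, rna_patch = c(10, 17), seed = 2)
  s <- make_complex(sp)
  lab <- label_interface_residues(s)
  prof <- scale_profile(make_profiles(sp, lab$label))
  ann <- data.frame(chain_id = "A", seq_index = 0:29,
                    asa = runif(30, 0, 150),
                    ss3 = sample(c("H", "E", "C"), 30, TRUE),
                    stringsAsFactors = FALSE)
  ft <- featurize_complex(s, list(A = prof), ann, encoding = "SpaPF", w = 15)
  expect_equal(dim(ft$X), c(30L, 300L))
  expect_equal(ft$y, lab$label)                 # label pass-through
  # per-row oracle: row i equals build_spapf on that residue's window
  for (i in c(1, 8, 30)) {
    ord <- spatial_neighbor_order(s, i, 15)
    expect_equal(ft$X[i, ], build_spapf(prof, ord, 15))
  }
  ft2 <- featurize_complex(s, NULL, ann, encoding = "SpawASA", w = 15)
  expect_equal(dim(ft2$X), c(30L, 15L))
  ft3 <- featurize_complex(s, NULL, ann, encoding = "SpaSecond", w = 15)
  expect_equal(dim(ft3$X), c(30L, 3L))
  expect_equal(unname(rowSums(ft3$X)), rep(1, 30))
  ft4 <- featurize_complex(s, list(A = prof), NULL, encoding = "SeqProfile",
                           w = 15)
  expect_equal(dim(ft4$X), c(30L, 300L))
  ft5 <- featurize_complex(s, NULL, ann, encoding = "SeqASA", w = 15)
  expect_equal(dim(ft5$X), c(30L, 15L))
  expect_error(featurize_complex(s, NULL, NULL, encoding = "SpaPF"),
               "requires profiles")
})

test_that("features are invariant to RNA residue order", {
  sp <- fixture_spec(n_residues = 20, rna_patch = c(6, 12), seed = 9)
  s <- make_complex(sp)
  lab <- label_interface_residues(s)
  prof <- scale_profile(make_profiles(sp, lab$label))
  ann <- make_annotations(sp, s, n_points = 120)
  # permute the RNA residues (reverse their order in the atom table)
  rna <- s$atoms[s$atoms$kind == "rna", ]
  rna$res_id <- max(rna$res_id) - rna$res_id
  s2 <- complex_structure(rbind(s$atoms[s$atoms$kind == "protein", ], rna),
                          "permuted")
  for (enc in c("SpaPF", "SpawASA", "SpaSecond")) {
    f1 <- featurize_complex(s, list(A = prof), ann, encoding = enc, w = 8)
    f2 <- featurize_complex(s2, list(A = prof), ann, encoding = enc, w = 8)
    expect_equal(f1$X, f2$X)
    expect_equal(f1$y, f2$y)
  }
})

test_that("feature table TSV round-trips with metadata", {
  sp <- fixture_spec(n_residues = 12, rna_patch = c(3, 6), seed = 4)
  s <- make_complex(sp)
  prof <- scale_profile(make_profiles(sp, label_interface_residues(s)$label))
  ft <- featurize_complex(s, list(A = prof), encoding = "SpaPF", w = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(ft, f)
  back <- read_feature_tsv(f)
  expect_equal(back$X, ft$X, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$y, ft$y)
  expect_equal(back$encoding, "SpaPF")
  expect_equal(back$w, 5L)
  expect_equal(back$metric, "ca")
})
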