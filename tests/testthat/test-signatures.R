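test_that("default panels carry the expected structure", {
  caf <- default_panel("caf4")
  expect_setequal(panel_genes(caf), c("FN1", "TGFB2", "TGFBR2", "TGFBI"))
  expect_true(all(caf$roles == "caf"))

  emt <- default_panel("emt_salt14")
  expect_length(panel_genes(emt, "mesenchymal"), 9)
  expect_length(panel_genes(emt, "epithelial"), 5)

  # FN1 is the only gene the EMT panel shares with the CAF index
  expect_identical(intersect(panel_genes(emt), panel_genes(caf)), "FN1")

  gs <- default_panel("emt76gs")
  expect_length(panel_genes(gs), 76)
  expect_true("CDH1" %in% panel_genes(gs))
})

test_that("panel construction and loading validate their input", {
  expect_error(gene_panel("p", c("A", "A"), c("caf", "caf")), "duplicate")
  expect_error(gene_panel("p", "A", "stromal"), "unknown panel role")
  # named default panels are count-validated, naming the shortfall
  expect_error(gene_panel("emt_salt14", c(paste0("M", 1:9), paste0("E", 1:4)),
                          c(rep("mesenchymal", 9), rep("epithelial", 4))),
               "9 mesenchymal \\+ 5 epithelial.*4 epithelial")
  expect_error(gene_panel("caf4", c("FN1", "TGFB2", "TGFBR2"), rep("caf", 3)),
               "exactly FN1, TGFB2, TGFBR2, TGFBI")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# my panel", "symbol\trole", "FN1\tcaf", "TGFB2\tcaf"), tsv)
  p <- load_panel(tsv, name = "mini")
  expect_identical(panel_genes(p), c("FN1", "TGFB2"))
  writeLines(c("symbol\trole", "FN1\tcaf", "FN1\tcaf"), tsv)
  expect_error(load_panel(tsv, name = "mini"), "duplicate")
})

test_that("EMT score is mesenchymal sum minus epithelial sum of log2 values", {
  g <- all14()
  ids <- c(g$mes, g$epi)
  m <- expr_matrix(toy_matrix(ids, c("s1", "s2"), 2), scale = "log2")
  sc <- score_emt_salt(m)
  expect_equal(unname(as.numeric(sc)), c(9 * 2 - 5 * 2, 8), tolerance = 1e-12)

  vals <- c(rep(0, 9), rep(1, 5))
  m2 <- expr_matrix(toy_matrix(ids, c("s1"), vals), scale = "log2")
  expect_equal(as.numeric(score_emt_salt(m2)), -5)

  # random matrix vs an independent spreadsheet-style row-sum oracle
  mr <- random_log2_matrix(ids, 6, seed = 301)
  sc_r <- score_emt_salt(mr)
  oracle <- sapply(seq_len(6), function(j) {
    s <- 0
    for (gg in g$mes) s <- s + unclass(mr)[gg, j]
    for (gg in g$epi) s <- s - unclass(mr)[gg, j]
    s
  })
  expect_equal(unname(as.numeric(sc_r)), unname(oracle), tolerance = 1e-12)

  # linear-scale input is refused
  expect_error(score_emt_salt(expr_matrix(toy_matrix(ids, "s1", 100),
                                          scale = "linear")), "log2")
})

test_that("missing EMT panel genes are omitted and reported", {
  g <- all14()
  ids <- setdiff(c(g$mes, g$epi), "TWIST2")
  mr <- random_log2_matrix(ids, 4, seed = 302)
  expect_warning(sc <- score_emt_salt(mr), "TWIST2")
  expect_identical(attr(sc, "genes_missing"), "TWIST2")
  # missing-gene consistency: score equals full-matrix score minus the
  # absent gene's contribution
  full <- random_log2_matrix(c(g$mes, g$epi), 4, seed = 303)
  sc_full <- score_emt_salt(full)
  reduced <- expr_matrix(unclass(full)[ids, ], scale = "log2")
  expect_warning(sc_red <- score_emt_salt(reduced), "TWIST2")
  expect_equal(as.numeric(sc_red),
               as.numeric(sc_full) - unname(unclass(full)["TWIST2", ]),
               tolerance = 1e-12)
})

test_that("CAF index is the sum of the four genes' log2 values", {
  m0 <- expr_matrix(toy_matrix(c("FN1", "TGFB2", "TGFBR2", "TGFBI"),
                               "s1", 0), scale = "log2")
  expect_equal(as.numeric(score_caf_index(m0)), 0)

  m1 <- expr_matrix(toy_matrix(c("FN1", "TGFB2", "TGFBR2", "TGFBI"),
                               "s1", c(5, 3, 2, 6)), scale = "log2")
  expect_equal(as.numeric(score_caf_index(m1)), 16)

  # random 20-gene x 8-sample matrix vs the independent 4-row sum oracle
  genes <- c("FN1", "TGFB2", "TGFBR2", "TGFBI", paste0("x", 1:16))
  mr <- random_log2_matrix(genes, 8, seed = 304)
  oracle <- unclass(mr)["FN1", ] + unclass(mr)["TGFB2", ] +
    unclass(mr)["TGFBR2", ] + unclass(mr)["TGFBI", ]
  expect_equal(unname(as.numeric(score_caf_index(mr))), unname(oracle),
               tolerance = 1e-12)

  # partial panels warn; fully absent panels error
  mp <- random_log2_matrix(c("FN1", "TGFB2", "zzz"), 3, seed = 305)
  expect_warning(scp <- score_caf_index(mp), "TGFBR2")
  expect_setequal(attr(scp, "genes_missing"), c("TGFBR2", "TGFBI"))
  mz <- random_log2_matrix(paste0("x", 1:5), 3, seed = 306)
  expect_error(score_caf_index(mz), "none of the CAF index genes")
})

test_that("76GS weights are CDH1 correlations applied to centered values", {
  # identical samples: mean-centering annihilates constants
  g <- panel_genes(default_panel("emt76gs"))[1:10]
  m_const <- expr_matrix(toy_matrix(g, paste0("s", 1:4), rep(1:10, 4)),
                         scale = "log2")
  suppressMessages(sc0 <- score_76gs(m_const))
  expect_equal(unname(as.numeric(sc0)), rep(0, 4), tolerance = 1e-12)

  # 3-gene toy: geneB = 2*CDH1, geneC = -CDH1 + offset -> weights (1,1,-1)
  cdh1 <- c(1, 2, 3, 4)
  vals <- rbind(CDH1 = cdh1, VIM = 2 * cdh1, FN1 = 10 - cdh1)
  colnames(vals) <- paste0("s", 1:4)
  m3 <- expr_matrix(vals, scale = "log2")
  panel3 <- gene_panel("toy3", c("CDH1", "VIM", "FN1"), rep("signature", 3))
  sc3 <- score_76gs(m3, panel3)
  w <- attr(sc3, "weights")
  expect_equal(unname(w), c(1, 1, -1), tolerance = 1e-12)  # CDH1 self-weight 1
  hand <- w["CDH1"] * (cdh1 - 2.5) + w["VIM"] * (2 * cdh1 - 5) +
    w["FN1"] * ((10 - cdh1) - 7.5)
  expect_equal(unname(as.numeric(sc3)), unname(hand), tolerance = 1e-12)

  # zero-variance gene gets weight 0
  vals2 <- rbind(vals, TGFB2 = rep(5, 4))
  m4 <- expr_matrix(vals2, scale = "log2")
  panel4 <- gene_panel("toy4", rownames(vals2), rep("signature", 4))
  expect_message(sc4 <- score_76gs(m4, panel4), "zero variance")
  expect_equal(unname(attr(sc4, "weights")["TGFB2"]), 0)
  expect_equal(as.numeric(sc4), as.numeric(sc3), tolerance = 1e-12)

  # CDH1 absence is fatal; single-sample cohorts are refused
  expect_error(score_76gs(random_log2_matrix(c("VIM", "FN1"), 4, 307)),
               "CDH1")
  expect_error(score_76gs(expr_matrix(vals[, 1, drop = FALSE],
                                      scale = "log2")), "2 samples")
})

test_that("score invariances: shift linearity, monotonicity, permutation", {
  g <- all14()
  genes <- unique(c(g$mes, g$epi, "TGFB2", "TGFBR2", "TGFBI"))
  m <- random_log2_matrix(genes, 6, seed = 308)

  # adding c to every log2 value shifts EMT by (9-5)c and CAF by 4c
  shifted <- expr_matrix(unclass(m) + 0.7, scale = "log2")
  expect_equal(as.numeric(score_emt_salt(shifted)),
               as.numeric(score_emt_salt(m)) + (9 - 5) * 0.7,
               tolerance = 1e-9)
  expect_equal(as.numeric(score_caf_index(shifted)),
               as.numeric(score_caf_index(m)) + 4 * 0.7, tolerance = 1e-9)
  # 76GS is invariant to per-gene constant shifts (mean-centering)
  pg <- gene_panel("sub", genes, rep("signature", length(genes)))
  mg <- expr_matrix(unclass(m) + seq_along(genes), scale = "log2")
  expect_equal(as.numeric(score_76gs(mg, pg)), as.numeric(score_76gs(m, pg)),
               tolerance = 1e-9)

  # raising one CAF gene in one sample raises only that sample's index
  bump <- unclass(m)
  bump["TGFB2", 3] <- bump["TGFB2", 3] + 1
  sc_b <- score_caf_index(expr_matrix(bump, scale = "log2"))
  sc_m <- score_caf_index(m)
  expect_gt(sc_b[3], sc_m[3])
  expect_equal(as.numeric(sc_b[-3]), as.numeric(sc_m[-3]), tolerance = 1e-12)

  # permuting sample columns permutes scores identically
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- expr_matrix(unclass(m)[, perm], scale = "log2")
  expect_equal(as.numeric(score_emt_salt(mp)),
               as.numeric(score_emt_salt(m))[perm], tolerance = 1e-12)
  expect_equal(as.numeric(score_caf_index(mp)),
               as.numeric(score_caf_index(m))[perm], tolerance = 1e-12)
})
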