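test_that("the significance filter applies both cuts strictly", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    log2fc  = c(1.32, 3, 1.0, -1.5, 0.5, -2),
    padj    = c(0.04, 0.06, 0.01, 0.02, 0.001, 0.05))
  fl <- filter_de(tab)
  expect_setequal(fl$up, "g1")       # padj 0.04, FC ~2.5
  expect_setequal(fl$down, "g4")     # g6 excluded: padj == 0.05 not < 0.05
  expect_false("g2" %in% fl$de)      # padj 0.06
  expect_false("g3" %in% fl$de)      # log2fc == 1 not > 1
  expect_false("g5" %in% fl$de)      # |FC| < 2
})

test_that("filter recovers the generator truth set exactly", {
  g <- gen_de_table(1000, frac_de = 0.1, seed = 3)
  fl <- filter_de(g$table)
  expect_setequal(fl$de, g$truth$de_genes)
  expect_setequal(fl$up, g$truth$up)
  expect_setequal(fl$down, g$truth$down)
})

test_that("filter counts match a brute-force row scan near the padj cut", {
  set.seed(41)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    log2fc = rnorm(200, 0, 2),
                    padj = pmin(pmax(0.05 + rnorm(200, 0, 0.01), 0), 1))
  fl <- filter_de(tab)
  n_up <- 0L; n_down <- 0L
  for (i in seq_len(nrow(tab))) {
    if (tab$padj[i] < 0.05 && tab$log2fc[i] > 1) n_up <- n_up + 1L
    if (tab$padj[i] < 0.05 && tab$log2fc[i] < -1) n_down <- n_down + 1L
  }
  expect_length(fl$up, n_up)
  expect_length(fl$down, n_down)
})

test_that("schema violations and missing padj are handled", {
  expect_error(filter_de(data.frame(gene_id = "a", log2fc = 1)), "missing")
  tab <- data.frame(gene_id = c("a", "b", "c"), log2fc = c(2, 2, 2),
                    padj = c(0.01, NA, 0.2))
  expect_message(fl <- filter_de(tab), "dropped")
  expect_setequal(fl$up, "a")
  dup <- data.frame(gene_id = c("a", "a"), log2fc = c(1, 2),
                    padj = c(0.1, 0.2))
  expect_error(filter_de(dup), "unique")
})

test_that("set overlaps match brute-force enumeration and identities", {
  expect_equal(overlap_sets(list(A = letters[1:5],
                                 B = letters[1:5]))$unique_counts,
               c(A = 0L, B = 0L))
  dis <- overlap_sets(list(A = letters[1:5], B = letters[10:16]))
  expect_equal(dis$pairwise["A", "B"], 0L)
  expect_equal(dis$unique_counts, c(A = 5L, B = 7L))
  set.seed(12)
  pool <- sprintf("gene%04d", 1:400)
  for (rep in 1:5) {
    sets <- list(A = sample(pool, 100), B = sample(pool, 100),
                 C = sample(pool, 100))
    ov <- overlap_sets(sets)
    # brute-force membership enumeration over the union
    uni <- unique(unlist(sets))
    for (i in names(sets)) for (j in names(sets)) {
      bf <- sum(vapply(uni, function(g) {
        g %in% sets[[i]] && g %in% sets[[j]]
      }, logical(1)))
      expect_equal(unname(ov$pairwise[i, j]), bf)
    }
    # inclusion-exclusion for every pair
    for (i in names(sets)) for (j in setdiff(names(sets), i)) {
      expect_equal(length(union(sets[[i]], sets[[j]])),
                   unname(ov$sizes[i] + ov$sizes[j] - ov$pairwise[i, j]))
    }
    # Venn regions partition the union
    expect_equal(sum(ov$patterns$count), length(uni))
  }
})

test_that("fold-change correlation matches the closed-form oracle", {
  toy_a <- data.frame(gene_id = letters[1:5],
                      log2fc = c(-2, -0.5, 0.3, 1.2, 2.5),
                      padj = rep(0.01, 5))
  toy_b <- data.frame(gene_id = letters[1:5],
                      log2fc = c(-1.7, -0.2, 0.1, 1.5, 2.1),
                      padj = rep(0.01, 5))
  fc <- fc_correlation(toy_a, toy_b)
  x <- toy_a$log2fc; y <- toy_b$log2fc
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fc$pearson_r, r_oracle, tolerance = 1e-12)
  expect_equal(fc$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(fc$intercept, mean(y) - slope_oracle * mean(x),
               tolerance = 1e-12)
  expect_equal(fc$n_matched, 5)
  # self and sign-flipped correlations
  expect_equal(fc_correlation(toy_a, toy_a)$pearson_r, 1)
  flip <- toy_a; flip$log2fc <- -flip$log2fc
  expect_equal(fc_correlation(toy_a, flip)$pearson_r, -1)
  # matched genes only; too few matches error
  expect_error(fc_correlation(toy_a[1:2, ], toy_b[1:2, ]), "fewer than 3")
  sub <- fc_correlation(toy_a, toy_b, gene_filter = letters[1:3])
  expect_equal(sub$n_matched, 3)
})

test_that("DESeq2-style headers map through the column config", {
  dir <- withr::local_tempdir()
  tab <- data.frame(gene = c("a", "b", "c"),
                    log2FoldChange = c(1.5, -2, 0.1),
                    padj = c(0.01, 0.02, 0.9))
  utils::write.table(tab, file.path(dir, "deseq.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  got <- read_de_table(file.path(dir, "deseq.tsv"),
                       col_map = c(gene_id = "gene",
                                   log2fc = "log2FoldChange"))
  expect_equal(names(got), c("gene_id", "log2fc", "padj"))
  fl <- filter_de(got)
  expect_setequal(fl$de, c("a", "b"))
})
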