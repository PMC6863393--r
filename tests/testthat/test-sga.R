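# SGA colony-size normalization, scoring, hit calling and rescue matrices.

make_uniform_plate <- function(size = 100, id = "p") {
  colony_plate(
    data.frame(
      row = rep(1:16, each = 24), col = rep(1:24, times = 16),
      gene = sprintf("g%03d", 1:384), size = size
    ),
    plate_id = id
  )
}

test_that("normalization is scale invariant and removes row/column effects", {
  p <- make_uniform_plate()
  n1 <- normalize_plate(p)
  expect_true(all(n1$size == 1))

  p3 <- p; p3$size <- p$size * 3
  expect_equal(normalize_plate(p3)$size, n1$size)

  pr <- p; pr$size[pr$row == 5] <- pr$size[pr$row == 5] * 2
  expect_equal(normalize_plate(pr)$size, rep(1, 384), tolerance = 1e-12)
})

test_that("normalization is idempotent once effects are removed", {
  genes <- sprintf("g%03d", 1:384)
  tr <- plate_truth(genes,
    plate_effects = 1.7, row_effects = runif(16, 0.5, 2),
    col_effects = runif(24, 0.5, 2), noise_sdlog = 0, seed = 21
  )
  ex <- gen_colony_experiment(tr, 1)
  n1 <- normalize_plate(ex$control[[1]])
  n2 <- normalize_plate(n1)
  expect_equal(n2$size, n1$size, tolerance = 1e-12)
})

test_that("plates with under 50% growth are flagged and excluded", {
  p <- make_uniform_plate()
  p$size[1:200] <- 0
  expect_warning(np <- normalize_plate(p), "50%")
  expect_true(isTRUE(attr(np, "excluded")))
})

test_that("log2 scores follow the ratio arithmetic with a lethal sentinel", {
  genes <- sprintf("g%03d", 1:100)
  tr <- plate_truth(genes,
    interaction_factors = c(g010 = 0.5, g020 = 0.25, g030 = 0)
  )
  ex <- gen_colony_experiment(tr, 1)
  sc <- interaction_scores(ex$query, ex$control)
  expect_equal(sc$score[sc$gene == "g010"], -1)
  expect_equal(sc$score[sc$gene == "g020"], -2)
  expect_equal(sc$score[sc$gene == "g040"], 0)
  expect_true(sc$lethal[sc$gene == "g030"])
  expect_identical(sc$score[sc$gene == "g030"], -Inf)
})

test_that("scores are invariant to global scaling of query or control", {
  genes <- sprintf("g%03d", 1:100)
  tr <- plate_truth(genes, interaction_factors = c(g010 = 0.5),
                    noise_sdlog = 0.05, seed = 4)
  ex <- gen_colony_experiment(tr, 2)
  sc <- interaction_scores(ex$query, ex$control)
  scaled <- lapply(ex$query, function(p) { p$size <- p$size * 7; p })
  sc2 <- interaction_scores(scaled, ex$control)
  expect_equal(sc2$score, sc$score, tolerance = 1e-12)
})

test_that("the hit cutoff is strict and lethal genes are hits", {
  sc <- data.frame(
    gene = c("a", "b", "c"), score = c(-1.0, -1.01, -Inf),
    n_replicates = 1, lethal = c(FALSE, FALSE, TRUE)
  )
  h <- call_hits(sc, cutoff = -1.0)
  expect_identical(h$hit, c(FALSE, TRUE, TRUE))
})

test_that("planted interactions are detected with high power and few false positives", {
  genes <- sprintf("g%03d", 1:96)
  hits_called <- 0; misses <- 0; fp <- 0; null_fp <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    tr <- plate_truth(genes,
      interaction_factors = c(g005 = 0.4, g010 = 0.9),
      noise_sdlog = 0.1, seed = 10000 + s
    )
    ex <- gen_colony_experiment(tr, 4)
    sc <- call_hits(interaction_scores(ex$query, ex$control))
    if (sc$hit[sc$gene == "g005"]) hits_called <- hits_called + 1
    if (sc$hit[sc$gene == "g010"]) fp <- fp + 1

    tr0 <- plate_truth(genes, noise_sdlog = 0.1, seed = 20000 + s)
    ex0 <- gen_colony_experiment(tr0, 4)
    sc0 <- call_hits(interaction_scores(ex0$query, ex0$control))
    null_fp <- null_fp + sum(sc0$hit)
  }
  expect_gte(hits_called / n_seeds, 0.95)  # power for factor 0.4
  expect_equal(fp, 0)                      # factor 0.9 never called
  expect_lt(null_fp / (n_seeds * length(genes)), 0.01)
})

test_that("rescue matrices keep base scores bitwise and flag rescues", {
  genes <- sprintf("g%03d", 1:96)  # four full rows: stable column medians
  tr <- plate_truth(genes, interaction_factors = c(g007 = 0.4),
                    noise_sdlog = 0, seed = 2)
  ex <- gen_colony_experiment(tr, 1)
  base <- interaction_scores(ex$query, ex$control)

  # construct restoring the factor to 1: gene rescued
  tr_full <- plate_truth(genes, noise_sdlog = 0, seed = 2)
  ex_full <- gen_colony_experiment(tr_full, 1)
  full <- interaction_scores(ex_full$query, ex_full$control)

  rm_ <- rescue_matrix(base, list(full_length = full, none_like = base))
  expect_identical(rm_$scores[, "none"],
                   setNames(base$score, base$gene))
  expect_true(rm_$rescued["g007", "full_length"])
  expect_false(rm_$rescued["g007", "none_like"])
  expect_true(all(rm_$rescued[setdiff(genes, "g007"), ]))
})
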