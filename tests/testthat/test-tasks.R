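test_that("analogies satisfy the parallelogram identity in every regime", {
  pool <- generate_analogy_pool(20L, 500L, seed = 1L)
  sets <- list(pool,
               translate_problems(pool, 2L),
               scale_problems(pool, 3L))
  for (ps in sets) {
    expect_true(all(ps$points$B - ps$points$A ==
                      ps$points$D - ps$points$C))
  }
})

test_that("problems respect their region bounds", {
  pool <- generate_analogy_pool(10L, 300L, seed = 2L)
  all_pts <- function(ps) {
    rbind(do.call(rbind, ps$points),
          cbind(as.vector(ps$foils[, , 1]), as.vector(ps$foils[, , 2])))
  }
  p <- all_pts(pool)
  expect_true(all(p >= 0 & p <= 9))
  tr <- translate_problems(pool, 3L)
  p <- all_pts(tr)
  expect_true(all(p >= 30 & p <= 39))
  sc <- scale_problems(pool, 4L)
  expect_true(all(do.call(rbind, sc$points) %% 4L == 0L))
  expect_true(all(all_pts(sc) >= 0 & all_pts(sc) <= 39))
  expect_equal(max(do.call(rbind, sc$points)), 4 * 9)
})

test_that("translation adds KM to every constituent and K = 0 is identity", {
  pool <- generate_analogy_pool(10L, 50L, seed = 3L)
  tr <- translate_problems(pool, 2L)
  for (nm in c("A", "B", "C", "D")) {
    expect_equal(tr$points[[nm]], pool$points[[nm]] + 20L)
  }
  expect_identical(translate_problems(pool, 0L), pool)
  expect_identical(scale_problems(pool, 1L)$points, pool$points)
})

test_that("foils are six distinct points that never equal the answer", {
  pool <- generate_analogy_pool(5L, 400L, seed = 4L)
  for (ps in list(pool, translate_problems(pool, 1L),
                  scale_problems(pool, 2L))) {
    ans <- problem_answers(ps)
    for (i in seq_len(ps$n)) {
      f <- ps$foils[i, , ]
      expect_equal(nrow(unique(f)), 6L)
      expect_false(any(f[, 1] == ans[i, 1] & f[, 2] == ans[i, 2]))
    }
  }
})

test_that("train and validation splits are disjoint at a 20% fraction", {
  pool <- generate_analogy_pool(20L, 1000L, seed = 5L)
  expect_equal(sum(pool$split == "val"), 200L)
  expect_equal(sum(pool$split == "train"), 800L)
  tr <- subset_problems(pool, "train")
  va <- subset_problems(pool, "val")
  key <- function(ps) paste(ps$points$A[, 1], ps$points$A[, 2],
                            ps$points$B[, 1], ps$points$B[, 2],
                            ps$points$C[, 1], ps$points$C[, 2])
  expect_equal(tr$n + va$n, pool$n)
  expect_true(length(intersect(which(pool$split == "train"),
                               which(pool$split == "val"))) == 0)
})

test_that("analogy start points are uniform over the training region", {
  pool <- generate_analogy_pool(10L, 20000L, seed = 6L)
  counts <- table(factor(pool$points$A[, 1] * 10 + pool$points$A[, 2],
                         levels = 0:99))
  p <- chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("arithmetic problems decompose their answers correctly", {
  add <- generate_arithmetic(10L, "add", K = 0L, n = 300L, seed = 7L)
  expect_true(all(add$points$A + add$points$B == add$points$C))
  expect_true(all(add$points$C >= 0 & add$points$C <= 9))
  mul <- generate_arithmetic(10L, "multiply", K = 2L, n = 300L, seed = 8L)
  nz <- mul$points$C != 0L
  expect_true(all((mul$points$A * mul$points$B)[nz] == mul$points$C[nz]))
  expect_true(all(mul$points$A[!nz] == 0L))
  expect_true(all(mul$points$C >= 20 & mul$points$C <= 29))
  # training split exists only for the training region
  expect_setequal(unique(add$split), c("train", "val"))
  expect_equal(unique(mul$split), "test")
  big <- generate_arithmetic(100L, "add", K = 3L, n = 100L, seed = 9L)
  expect_true(all(big$points$C >= 300 & big$points$C <= 399))
})

test_that("candidate assembly hides the answer uniformly among foils", {
  pool <- generate_analogy_pool(10L, 3500L, seed = 10L)
  cand <- assemble_candidates(pool)
  expect_equal(dim(cand$candidates), c(3500L, 7L, 2L))
  expect_true(all(cand$target >= 1 & cand$target <= 7))
  ans <- problem_answers(pool)
  hits <- vapply(seq_len(pool$n), function(i) {
    sum(cand$candidates[i, , 1] == ans[i, 1] &
          cand$candidates[i, , 2] == ans[i, 2])
  }, numeric(1))
  expect_true(all(hits == 1))
  expect_true(all(cand$candidates[cbind(seq_len(pool$n), cand$target, 1)] ==
                    ans[, 1]))
  p <- chisq.test(table(factor(cand$target, levels = 1:7)))$p.value
  expect_gt(p, 0.01)
})

test_that("generation is reproducible from the seed", {
  a <- generate_analogy_pool(15L, 200L, seed = 42L)
  b <- generate_analogy_pool(15L, 200L, seed = 42L)
  expect_identical(a, b)
  c <- generate_analogy_pool(15L, 200L, seed = 43L)
  expect_false(identical(a$points$A, c$points$A))
  expect_identical(assemble_candidates(a), assemble_candidates(b))
  x <- generate_arithmetic(12L, "multiply", 1L, 100L, seed = 9L)
  y <- generate_arithmetic(12L, "multiply", 1L, 100L, seed = 9L)
  expect_identical(x, y)
})

test_that("regions too small for seven candidates are rejected", {
  expect_error(generate_analogy_pool(2L), "at least 7")
  expect_error(generate_arithmetic(2L, "add"), "at least 7")
})
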