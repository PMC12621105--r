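# Greedy-soup parameter averaging: arithmetic, pool ordering, the acceptance
# rule, and its guarantees.

test_that("parameter averaging is the entry-wise mean across components", {
  a <- list(v_w = matrix(1, 2, 2), t_w = c(1, 3), h_w = 0)
  b <- list(v_w = matrix(3, 2, 2), t_w = c(3, 1), h_w = 2)
  avg <- averageParameters(list(a, b))
  expect_equal(avg$v_w, matrix(2, 2, 2))
  expect_equal(avg$t_w, c(2, 2))
  expect_equal(avg$h_w, 1)
  # identity: mean of identical sets is the set
  expect_equal(averageParameters(list(a, a, a)), a)
  # three-set arithmetic
  cc <- list(v_w = matrix(2, 2, 2), t_w = c(2, 2), h_w = 1)
  expect_equal(averageParameters(list(a, b, cc))$h_w, 1)
  expect_error(averageParameters(list()), class = "bivqa_contract_error")
  expect_error(averageParameters(list(a, list(v_w = matrix(1, 3, 3)))),
               class = "bivqa_contract_error")
  bad <- a; bad$v_w <- matrix(1, 3, 2)
  expect_error(averageParameters(list(a, bad)), class = "bivqa_contract_error")
})

test_that("the top-k pool sorts by accuracy with stable ties", {
  cks <- list(param_checkpoint("c1", list(w = 1), 0.80, 1),
              param_checkpoint("c2", list(w = 2), 0.85, 2),
              param_checkpoint("c3", list(w = 3), 0.83, 3))
  pool <- topKPool(cks, 3)
  expect_identical(vapply(pool, function(x) x@id, ""), c("c2", "c3", "c1"))
  expect_identical(topKPool(cks, 1)[[1]]@id, "c2")  # argmax of ValAcc
  ties <- list(param_checkpoint("t1", list(w = 1), 0.8, 1),
               param_checkpoint("t2", list(w = 2), 0.8, 2))
  expect_identical(vapply(topKPool(ties, 2), function(x) x@id, ""),
                   c("t1", "t2"))
  expect_error(topKPool(list(), 3), class = "bivqa_contract_error")
})

test_that("a pool of identical checkpoints is fully accepted and returns the
           shared parameters", {
  params <- list(v_w = matrix(1:4 / 4, 2, 2), h_w = c(0.3, 0.7))
  cks <- lapply(1:3, function(i)
    param_checkpoint(paste0("c", i), params, 0.7, i))
  soup <- greedySoup(cks, function(p) 0.7)
  expect_length(ingredients(soup), 3)
  expect_equal(modelParameters(soup), params)
  expect_equal(valAccuracy(soup), 0.7)
})

test_that("a pool of one yields that checkpoint unchanged", {
  ck <- param_checkpoint("only", list(w = c(1, 2)), 0.6)
  soup <- greedySoup(list(ck), function(p) 0.6)
  expect_identical(ingredients(soup), "only")
  expect_equal(modelParameters(soup), ck@params)
})

test_that("a constant evaluator accepts every candidate (plain average);
           the strict rule accepts none", {
  cks <- lapply(1:4, function(i)
    param_checkpoint(paste0("c", i), list(w = as.numeric(i)), 0.9 - i / 100, i))
  soup <- greedySoup(cks, function(p) 0.5)
  expect_length(ingredients(soup), 4)
  expect_equal(modelParameters(soup)$w, mean(1:4))
  strict <- greedySoup(cks, function(p) 0.5, rule = "strict")
  expect_length(ingredients(strict), 1)
})

# Linear classifiers over a fixed 20-point 2-class validation set; the
# evaluator scores sign agreement.
linear_fixture <- function() {
  set.seed(13)
  X <- cbind(rnorm(20), rnorm(20))
  y <- ifelse(X %*% c(1, 1) + rnorm(20, sd = 0.4) > 0, 1, -1)
  evaluator <- function(params) mean(sign(drop(X %*% params$h_w)) == y)
  list(X = X, y = y, evaluator = evaluator)
}

test_that("greedy soup matches a brute-force prefix-subset oracle on linear
           classifiers", {
  fx <- linear_fixture()
  thetas <- list(c(2, 0.5), c(0.5, 2), c(3, -2))
  accs <- vapply(thetas, function(th) fx$evaluator(list(h_w = th)), 0)
  ord <- order(-accs)
  thetas <- thetas[ord]; accs <- accs[ord]
  cks <- lapply(1:3, function(i)
    param_checkpoint(paste0("c", i), list(h_w = thetas[[i]]), accs[i], i))

  # independent oracle: simulate the acceptance rule over the 4
  # prefix-respecting subsets {1}, {1,2}, {1,3}, {1,2,3}
  subset_acc <- function(ix) fx$evaluator(list(h_w = Reduce(`+`, thetas[ix]) / length(ix)))
  sel <- 1L
  cur <- subset_acc(1L)
  for (i in 2:3) {
    a <- subset_acc(c(sel, i))
    if (a >= cur) { sel <- c(sel, i); cur <- a }
  }

  soup <- greedySoup(cks, fx$evaluator)
  expect_identical(ingredients(soup), paste0("c", sel))
  expect_equal(modelParameters(soup)$h_w, Reduce(`+`, thetas[sel]) / length(sel))
  expect_equal(valAccuracy(soup), cur)
  # the fixture is informative: the greedy choice is a strict subset decision
  expect_true(length(sel) < 3 || cur > subset_acc(1L))
})

test_that("the audited soup accuracy is non-decreasing and the final soup
           never falls below its best single ingredient", {
  fx <- linear_fixture()
  set.seed(17)
  for (rep_i in 1:10) {
    thetas <- lapply(1:5, function(i) rnorm(2))
    cks <- lapply(seq_along(thetas), function(i)
      param_checkpoint(paste0("c", i), list(h_w = thetas[[i]]),
                       fx$evaluator(list(h_w = thetas[[i]])), i))
    soup <- greedySoup(topKPool(cks, 3), fx$evaluator)
    audit <- soupAudit(soup)
    expect_false(is.unsorted(audit$soup_accuracy))
    best_single <- max(vapply(cks, valAccuracy, 0))
    expect_gte(valAccuracy(soup) + 1e-12, best_single)
  }
})

test_that("evaluator failures are propagated with the candidate id", {
  cks <- list(param_checkpoint("good", list(w = 1), 0.9, 1),
              param_checkpoint("bad", list(w = 2), 0.8, 2))
  n_call <- 0
  ev <- function(p) {
    n_call <<- n_call + 1
    if (n_call > 1) stop("boom")
    0.9
  }
  expect_error(greedySoup(cks, ev), regexp = "bad")
})
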