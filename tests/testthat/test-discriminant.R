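make_gaussians <- function(n, d, p = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p), n, p) + rep(c(d, rep(0, p - 1)), each = n))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = factor(rep(c("a", "b"), each = n)))
}

test_that("the Fisher direction equals the generalized eigenvector", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40; p <- 4
    A <- matrix(rnorm(p * p), p, p)
    X <- rbind(matrix(rnorm(n * p), n, p) %*% A,
               matrix(rnorm(n * p), n, p) %*% A +
                 rep(rnorm(p, 0, 2), each = n))
    colnames(X) <- paste0("f", 1:p)
    y <- factor(rep(0:1, each = n))
    m <- fit_lda(X, y)
    # independent route: leading eigenvector of SW^-1 SB
    ev <- eigen(solve(m$SW) %*% m$SB)
    w2 <- Re(ev$vectors[, which.max(Re(ev$values))])
    cosine <- abs(sum(m$w * w2)) / sqrt(sum(w2^2))
    expect_gt(cosine, 1 - 1e-10)
    # J is scale invariant and maximal at w
    expect_equal(fisher_criterion(m, 3.7 * m$w), fisher_criterion(m))
    rand <- rnorm(p)
    expect_gte(fisher_criterion(m) + 1e-9, fisher_criterion(m, rand))
  }
})

test_that("LDA predictions agree with an independent reference fit", {
  skip_if_not_installed("MASS")
  for (seed in 1:5) {
    g <- make_gaussians(60, 1.2, p = 3, seed = seed)
    m <- fit_lda(g$X, g$y)
    ref <- MASS::lda(g$X, g$y)
    newx <- make_gaussians(50, 1.2, p = 3, seed = seed + 100)$X
    expect_equal(as.character(predict(m, newx)),
                 as.character(predict(ref, newx)$class))
  }
})

test_that("degenerate and separable inputs behave as contracted", {
  # identical class distributions: no separation
  X <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- factor(rep(c("a", "b"), each = 4))
  m <- fit_lda(X, y)
  expect_lt(fisher_criterion(m), 1e-20)
  # widely separated 1-D classes: perfect LOO
  X2 <- matrix(c(0, 1, 10, 11), ncol = 1, dimnames = list(NULL, "f1"))
  y2 <- factor(c("a", "a", "b", "b"))
  rep2 <- loo_validate(rbind(X2, X2 + 0.1), factor(rep(c("a","a","b","b"), 2)))
  expect_equal(rep2$accuracy_loo, 1)
  expect_error(fit_lda(X2, factor(rep("a", 4))), "two classes")
  # duplicated feature triggers the ridge fallback, not an error
  X3 <- cbind(f1 = rnorm(20), f2 = 0)
  X3 <- cbind(X3, f3 = X3[, 1])
  m3 <- fit_lda(X3, factor(rep(c("a", "b"), 10)))
  expect_gt(m3$ridge, 0)
})

test_that("hold-out accuracy approaches the Bayes rate for known Gaussians", {
  g <- make_gaussians(2000, 1, seed = 7)
  rep <- holdout_validate(g$X, g$y, repeats = 10, seed = 7)
  expect_equal(rep$accuracy, pnorm(0.5), tolerance = 0.05)
  # determinism contract
  rep2 <- holdout_validate(g$X, g$y, repeats = 10, seed = 7)
  expect_identical(rep$per_repeat_accuracy, rep2$per_repeat_accuracy)
  # separable data: perfect F-score with zero spread
  Xs <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60) + 20, 30, 2))
  colnames(Xs) <- c("f1", "f2")
  ys <- factor(rep(c("a", "b"), each = 30))
  rs <- holdout_validate(Xs, ys, repeats = 5, seed = 1)
  expect_equal(rs$f_score_mean, 1)
  expect_equal(rs$f_score_sd, 0)
})

test_that("stepwise selection finds signal and ignores noise", {
  hits <- 0; clean <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 100
    X <- cbind(inf = c(rnorm(n), rnorm(n) + 2),
               n1 = rnorm(2 * n), n2 = rnorm(2 * n))
    y <- factor(rep(c("a", "b"), each = n))
    s <- stepwise_select(X, y)
    if ("inf" %in% s$selected) hits <- hits + 1
    if (!any(c("n1", "n2") %in% s$selected)) clean <- clean + 1
  }
  expect_gte(hits, 19)
  expect_gte(clean, 17)

  # all-noise input: empty selection, flagged as chance level
  set.seed(99)
  Xn <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("n1", "n2")))
  s <- stepwise_select(Xn, factor(rep(c("a", "b"), 50)))
  expect_true(s$chance_level)
  expect_length(s$selected, 0)

  # duplicated informative feature: exactly one copy selected
  set.seed(5)
  inf <- c(rnorm(100), rnorm(100) + 2)
  Xd <- cbind(inf1 = inf, inf2 = inf)
  s <- stepwise_select(Xd, factor(rep(c("a", "b"), each = 100)))
  expect_length(intersect(c("inf1", "inf2"), s$selected), 1L)
})

test_that("leave-one-out is honest about optimism and the null", {
  # LOO accuracy should rarely exceed resubstitution accuracy
  worse <- 0
  for (seed in 1:25) {
    g <- make_gaussians(15, 0.8, p = 3, seed = seed)
    r <- loo_validate(g$X, g$y)
    if (r$accuracy_loo <= r$accuracy + 1e-9) worse <- worse + 1
  }
  expect_gte(worse, 20)

  # permuted labels give chance-level LOO accuracy
  set.seed(123)
  g <- make_gaussians(100, 2, seed = 3)
  yp <- sample(g$y)
  r <- loo_validate(g$X, yp)
  expect_lt(abs(r$accuracy_loo - 0.5), 3 * sqrt(0.25 / 200))

  # grouped units: folds leave out whole patients
  g <- make_gaussians(30, 10, seed = 4)
  units <- rep(paste0("p", 1:12), each = 5)
  r <- loo_validate(g$X, g$y, unit_ids = units)
  expect_equal(r$n_units, 12)
  expect_equal(r$accuracy_loo, 1)
})

test_that("f_score arithmetic matches direct computation", {
  expect_equal(f_score(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(f_score(matrix(c(25, 25, 25, 25), 2)), 0.5)
  cm <- matrix(c(40, 10, 5, 45), 2, byrow = TRUE)
  pc <- f_score(cm, "per_class")
  expect_equal(unname(pc[1]), 2 * (40/45) * (40/50) / (40/45 + 40/50))
  expect_equal(f_score(cm), mean(pc))
  # symmetric confusion: macro F equals either class F
  cs <- matrix(c(30, 10, 10, 30), 2)
  expect_equal(f_score(cs), unname(f_score(cs, "per_class")[1]))
  # empty predicted class yields 0, not NaN
  z <- matrix(c(10, 10, 0, 0), 2)
  expect_equal(unname(f_score(z, "per_class")[2]), 0)
  expect_error(f_score(matrix(c(-1, 0, 0, 1), 2)), "nonnegative")
})

test_that("patient aggregation averages cells and rejects orphans", {
  feats <- data.frame(cell_id = c("c1", "c2", "c3"),
                      lbp_mean = c(10, 12, 7), lbp_entropy = c(1, 3, 2))
  man <- data.frame(cell_id = c("c1", "c2", "c3"),
                    patient_id = c("P1", "P1", "P2"),
                    group = c("SCD", "SCD", "control"))
  agg <- aggregate_per_patient(feats, man)
  expect_equal(agg$lbp_mean[agg$patient_id == "P1"], 11)
  expect_equal(agg$n_cells, c(2L, 1L))
  expect_equal(agg$lbp_mean[agg$patient_id == "P2"], 7)  # single cell: identity
  # permuting cell order changes nothing
  agg2 <- aggregate_per_patient(feats[c(3, 1, 2), ], man)
  expect_equal(agg, agg2)
  man$cell_id[3] <- "other"
  expect_error(aggregate_per_patient(feats, man), "orphan")
})
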