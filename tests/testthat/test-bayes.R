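random_binary_data <- function(n, v, seed) {
  set.seed(seed)
  x <- matrix(rbinom(n * v, 1, runif(1, 0.2, 0.8)), n, v,
              dimnames = list(NULL, paste0("c", seq_len(v))))
  y <- c(0L, 1L, rbinom(n - 2, 1, 0.6))
  list(x = x, y = y)
}

test_that("conditionals match the smoothed closed form", {
  x <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), ncol = 1,
              dimnames = list(NULL, "c1"))
  y <- c(1, 1, 1, 1, 1, 1, 0, 0, 0)  # clique in 4 of 6 positives
  m0 <- clique_nb(x, y, alpha = 0)
  expect_equal(unname(m0$cond["1", 1]), 2 / 3)
  expect_equal(m0$prior, 2 / 3)
  x2 <- matrix(0L, nrow = 3, ncol = 1); y2 <- c(1, 1, 0)
  # present in 0 of 2 positives... use 3 positives + 1 negative
  x3 <- matrix(c(0, 0, 0, 1), ncol = 1); y3 <- c(1, 1, 1, 0)
  m1 <- clique_nb(x3, y3, alpha = 1)
  expect_equal(unname(m1$cond["1", 1]), (0 + 1) / (3 + 2))
  expect_error(clique_nb(x, y, alpha = -1), "non-negative")
  expect_error(clique_nb(x, rep(1, 9)), "both classes")
})

test_that("posterior equals the prior when evidence is absent or uninformative", {
  d <- random_binary_data(30, 4, 1)
  # V = 0: no evidence
  m <- clique_nb(d$x[, integer(0), drop = FALSE], d$y)
  expect_equal(unname(predict(m, matrix(0L, 1, 0))), m$prior)
  # identical conditionals for both classes
  m2 <- clique_nb(d$x, d$y, alpha = 1)
  m2$cond["0", ] <- m2$cond["1", ]
  post <- predict(m2, d$x[1:5, ])
  expect_equal(unname(post), rep(m2$prior, 5))
})

test_that("log-space posterior matches the direct-product oracle at small V", {
  for (seed in 1:10) {
    d <- random_binary_data(40, sample(1:8, 1), seed)
    m <- clique_nb(d$x, d$y, alpha = 0.7)
    post <- predict(m, d$x)
    p1 <- m$cond["1", ]; p0 <- m$cond["0", ]
    for (i in 1:5) {
      xi <- d$x[i, ]
      num <- prod(ifelse(xi == 1, p1, 1 - p1)) * m$prior
      den <- num + prod(ifelse(xi == 1, p0, 1 - p0)) * (1 - m$prior)
      expect_equal(post[i], num / den, tolerance = 1e-9)
    }
  }
})

test_that("posteriors agree with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  d <- random_binary_data(60, 5, 42)
  m <- clique_nb(d$x, d$y, alpha = 1)
  df <- as.data.frame(lapply(as.data.frame(d$x), factor, levels = 0:1))
  ref <- e1071::naiveBayes(df, factor(d$y, levels = 0:1), laplace = 1)
  rpost <- predict(ref, df, type = "raw")[, "1"]
  expect_equal(unname(predict(m, d$x)), unname(rpost), tolerance = 1e-9)
})

test_that("unsmoothed marginals equal empirical fractions on 100 random datasets", {
  for (seed in 1:100) {
    d <- random_binary_data(sample(20:60, 1), sample(1:6, 1), seed + 500)
    # ensure every clique occurs at least once
    d$x[1, ] <- 1L
    m <- clique_nb(d$x, d$y, alpha = 0)
    marg <- marginal_probability(m)
    emp <- colSums(d$x[d$y == 1, , drop = FALSE]) / colSums(d$x)
    expect_equal(unname(marg), unname(emp), tolerance = 1e-12)
  }
})

test_that("marginal limits: ubiquitous clique gives the prior, pure clique gives 1", {
  x <- cbind(everywhere = rep(1L, 10),
             only_pos = c(rep(1L, 4), rep(0L, 6)))
  y <- c(rep(1L, 6), rep(0L, 4))
  m <- clique_nb(x, y, alpha = 0)
  marg <- marginal_probability(m)
  expect_equal(unname(marg["everywhere"]), m$prior)
  expect_equal(unname(marg["only_pos"]), 1)
  # clique in 4 positives + 1 negative out of 10 molecules, 6 positive
  x2 <- cbind(c1 = c(1, 1, 1, 1, 0, 0, 1, 0, 0, 0))
  m2 <- clique_nb(x2, y, alpha = 0)
  expect_equal(unname(marginal_probability(m2, "c1")), 0.8)
  # absent clique is undefined under alpha = 0
  x3 <- cbind(gone = rep(0L, 10))
  m3 <- clique_nb(x3, y, alpha = 0)
  expect_error(marginal_probability(m3), "undefined")
})

test_that("marginals are invariant to duplicating the dataset", {
  d <- random_binary_data(40, 5, 9)
  d$x[1, ] <- 1L
  m1 <- clique_nb(d$x, d$y, alpha = 0)
  m2 <- clique_nb(rbind(d$x, d$x), c(d$y, d$y), alpha = 0)
  expect_equal(marginal_probability(m1), marginal_probability(m2),
               tolerance = 1e-12)
})

test_that("adding a positive molecule containing a clique never lowers its marginal", {
  set.seed(17)
  for (rep in 1:20) {
    d <- random_binary_data(30, 3, rep + 900)
    d$x[1, ] <- 1L
    for (alpha in c(0, 1)) {
      m <- clique_nb(d$x, d$y, alpha = alpha)
      base <- marginal_probability(m, 1)
      x2 <- rbind(d$x, c(1L, d$x[2, -1]))
      m2 <- clique_nb(x2, c(d$y, 1L), alpha = alpha)
      expect_gte(marginal_probability(m2, 1), base - 1e-12)
    }
  }
})

test_that("clique report splits enhancers and suppressors at the thresholds", {
  x <- cbind(hi = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
             lo = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1),
             mid = rep(1L, 10))
  y <- c(rep(1L, 5), rep(0L, 5))
  # hi: 4 pos / 0 neg -> 1.0 ; lo: 1 pos / 3 neg -> 0.25... make it cleaner
  x[, "lo"] <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)  # 0 pos, 5 neg -> 0
  m <- clique_nb(x, y, alpha = 0)
  voc <- data.frame(index = 0:2, fragment = c("hi", "lo", "mid"),
                    doc_freq = c(4L, 5L, 10L))
  class(voc) <- c("clique_vocabulary", "data.frame")
  rep_ <- clique_report(m, voc, min_doc_freq = 1, compute_clogp = FALSE)
  expect_equal(rep_$enhancers$fragment, "hi")
  expect_equal(rep_$suppressors$fragment, "lo")
  expect_equal(nrow(rep_$full), 3L)  # full export covers the vocabulary
  expect_error(clique_report(m, voc, hi = 0.2, lo = 0.8), "greater than")
  # document-frequency filter removes rows from the labelled tables only
  rep2 <- clique_report(m, voc, min_doc_freq = 5, compute_clogp = FALSE)
  expect_equal(nrow(rep2$enhancers), 0L)  # "hi" has doc_freq 4
  expect_equal(nrow(rep2$full), 3L)
})

test_that("marginal 0.5 cliques appear in neither labelled table", {
  x <- cbind(even = c(1, 1, 0, 0))
  y <- c(1, 0, 1, 0)
  m <- clique_nb(x, y, alpha = 0)
  voc <- data.frame(index = 0L, fragment = "even", doc_freq = 2L)
  class(voc) <- c("clique_vocabulary", "data.frame")
  rep_ <- clique_report(m, voc, min_doc_freq = 1, compute_clogp = FALSE)
  expect_equal(nrow(rep_$enhancers), 0L)
  expect_equal(nrow(rep_$suppressors), 0L)
})

test_that("naive-Bayes scores feed the metrics report", {
  d <- random_binary_data(80, 6, 123)
  m <- clique_nb(d$x, d$y)
  rep_ <- compute_metrics(d$y, predict(m, d$x))
  expect_true(all(c(rep_$sn, rep_$sp, rep_$auc) >= 0))
  expect_true(rep_$mcc >= -1 && rep_$mcc <= 1)
})
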