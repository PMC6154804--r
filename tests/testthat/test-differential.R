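# Differential modification, expression, diurnal rhythm, and set overlap.

test_that("modification calls require the fold change in both replicates", {
  ctl <- rbind(g1 = c(10, 10), g2 = c(10, 10), g3 = c(0, 0))
  trt <- rbind(g1 = c(20, 22), g2 = c(14, 20), g3 = c(5, 5))
  res <- diff_modification(ctl, trt, epsilon = 0.1)
  expect_equal(as.character(res$call[1]), "up")      # FCs ~1.99, 2.19
  expect_equal(as.character(res$call[2]), "unchanged")  # rep1 FC ~1.40
  res1 <- diff_modification(ctl, trt, epsilon = 1)
  expect_equal(res1$fc_rep1[3], 6)  # (5+1)/(0+1), pseudocount bounds FC
  expect_equal(as.character(res1$call[3]), "up")
  expect_error(diff_modification(ctl[, 1, drop = FALSE], trt), "two replicates")
  expect_error(diff_modification(ctl, trt, epsilon = 0), "epsilon")
})

test_that("swapping conditions mirrors modification calls exactly", {
  set.seed(3)
  a <- matrix(rpois(400, 20), ncol = 2,
              dimnames = list(paste0("g", 1:200), NULL))
  b <- matrix(rpois(400, 20) * rep(sample(c(1, 4), 200, TRUE), 2),
              ncol = 2, dimnames = list(paste0("g", 1:200), NULL))
  fwd <- diff_modification(a, b)
  rev <- diff_modification(b, a)
  expect_equal(fwd$call == "up", rev$call == "down")
  expect_equal(fwd$call == "down", rev$call == "up")
  expect_equal(fwd$log2fc, -rev$log2fc)
})

test_that("identical expression groups yield no DE calls", {
  m <- matrix(rpois(600, 30), ncol = 3,
              dimnames = list(paste0("g", 1:200), NULL))
  res <- diff_expression(m, m)
  expect_true(all(res$call == "unchanged"))
  expect_true(all(res$log2fc == 0))
})

test_that("large fold change without both thresholds is not called", {
  # one gene at FC 3 with a tiny p-value stays unchanged (fails FC > 4)
  set.seed(11)
  base <- matrix(rpois(3 * 500, 100), ncol = 3,
                 dimnames = list(paste0("g", 1:500), NULL))
  trt <- base
  trt[1, ] <- rpois(3, 300)
  res <- diff_expression(base, trt, fc_threshold = 4)
  expect_lt(res$fdr[1], 0.05)
  expect_equal(as.character(res$call[1]), "unchanged")
  res2 <- diff_expression(base, trt, fc_threshold = 2)
  expect_equal(as.character(res2$call[1]), "up")
})

test_that("adjusted p-values are monotone in raw p-values", {
  set.seed(21)
  a <- matrix(rnbinom(2000 * 3, mu = 50, size = 20), ncol = 3)
  b <- matrix(rnbinom(2000 * 3, mu = 50, size = 20), ncol = 3)
  res <- diff_expression(a, b)
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
})

test_that("precomputed p-values can replace the internal test", {
  a <- matrix(rpois(100 * 2, 50), ncol = 2,
              dimnames = list(paste0("g", 1:100), NULL))
  b <- a; b[1, ] <- b[1, ] * 10
  p <- c(1e-10, runif(99, 0.5, 1))
  res <- diff_expression(a, b, p_values = p)
  expect_equal(res$p_value, p)
  expect_equal(as.character(res$call[1]), "up")
})

test_that("welch mode matches stats::t.test on a small matrix", {
  set.seed(5)
  a <- matrix(rpois(20 * 4, 40), ncol = 4)
  b <- matrix(rpois(20 * 4, 55), ncol = 4)
  res <- diff_expression(a, b, method = "welch")
  for (i in c(1, 7, 20)) {
    pt <- t.test(log2(b[i, ] + 1), log2(a[i, ] + 1))$p.value
    expect_equal(res$p_value[i], pt)
  }
})

test_that("constant genes are never diurnal and cycling is label-invariant", {
  set.seed(31)
  n <- 400
  tp <- rep(c("T00", "T06", "T12", "T18"), each = 2)
  mu <- matrix(rep(2^rnorm(n, 6, 1), 8), ncol = 8)
  # plant a clean sinusoid in the first 40 genes, aligned to time points
  amp <- 2
  for (i in 1:40) {
    off <- amp / 2 * sin(2 * pi * (0:3) / 4 + pi / 4)
    mu[i, ] <- mu[i, ] * 2^rep(off, each = 2)
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 100), ncol = 8,
                   dimnames = list(paste0("g", 1:n), NULL))
  di <- diurnal_classification(counts, tp)
  expect_true(all(!di$diurnal[41:n]))
  expect_gt(mean(di$diurnal[1:40]), 0.8)
  # cyclic relabeling of time points leaves the classification unchanged
  relab <- c(T00 = "T06", T06 = "T12", T12 = "T18", T18 = "T00")
  di2 <- diurnal_classification(counts, relab[tp])
  expect_equal(di2$n_significant, di$n_significant)
  expect_error(diurnal_classification(counts, rep(c("a", "b"), 4)),
               "4 time points")
})

test_that("changed-set overlaps count intersections and percentages", {
  mk <- function(up, down, universe = paste0("g", 1:100)) {
    data.frame(gene_id = universe,
               call = factor(ifelse(universe %in% up, "up",
                                    ifelse(universe %in% down, "down",
                                           "unchanged")),
                             c("up", "down", "unchanged")))
  }
  r <- list(A = mk(paste0("g", 1:10), paste0("g", 51:60)),
            B = mk(paste0("g", 6:15), paste0("g", 51:60)),
            C = mk(paste0("g", 90:99), character(0)))
  ov <- changed_set_overlap(r)
  ab_up <- ov[ov$direction == "up" & ov$sets == "A&B", ]
  expect_equal(ab_up$n_intersection, 5)
  expect_equal(ab_up$pct_of_A, 50)
  abc_up <- ov[ov$direction == "up" & ov$sets == "A&B&C", ]
  expect_equal(abc_up$n_intersection, 0)
  ab_dn <- ov[ov$direction == "down" & ov$sets == "A&B", ]
  expect_equal(ab_dn$n_intersection, 10)
  expect_equal(ab_dn$pct_of_B, 100)
  # random independent sets hit the hypergeometric expectation
  set.seed(8)
  U <- paste0("g", 1:2000)
  inter <- replicate(300, {
    s1 <- sample(U, 200); s2 <- sample(U, 300)
    length(intersect(s1, s2))
  })
  expect_lt(abs(mean(inter) - 200 * 300 / 2000), 2)
})
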