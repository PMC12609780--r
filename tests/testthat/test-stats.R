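test_that("pearsonWithCi: hand dataset, perfect linearity, cor.test cross-check", {
  # hand computation: x = 1..5, y = (2,1,4,3,5): Sxy = 8, Sxx = Syy = 10
  h <- pearsonWithCi(1:5, c(2, 1, 4, 3, 5))
  expect_equal(h$r, 0.8, tolerance = 1e-12)
  expect_equal(h$ciLow, tanh(atanh(0.8) - qnorm(0.975) / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(h$ciHigh, tanh(atanh(0.8) + qnorm(0.975) / sqrt(2)),
               tolerance = 1e-12)
  # independent implementation agreement
  ct <- cor.test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(h$p, ct$p.value, tolerance = 1e-10)
  expect_equal(c(h$ciLow, h$ciHigh), as.numeric(ct$conf.int),
               tolerance = 1e-10)
  # perfect linear relation
  pl <- pearsonWithCi(1:10, 2 * (1:10) + 1)
  expect_equal(pl$r, 1)
  expect_lt(pl$p, 1e-12)
  expect_error(pearsonWithCi(1:3, 1:3), "at least 4")
  expect_error(pearsonWithCi(rep(1, 5), 1:5), "zero-variance")
})

test_that("blandAltman: closed-form identities and antisymmetry", {
  # constant offset: limits collapse onto the bias
  ba <- blandAltman(c(1, 2, 3) + 0.01, c(1, 2, 3))
  expect_equal(ba$bias, 0.01)
  expect_equal(ba$sd, 0)
  expect_equal(ba$loaLow, ba$loaHigh)
  # two-point: d = (-1, 1) -> bias 0, sd sqrt(2), LoA +/- 1.96 sqrt(2)
  ba2 <- blandAltman(c(0, 2), c(1, 1))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(ba2$loaHigh, 1.96 * sqrt(2), tolerance = 1e-12)
  # antisymmetry under swapping methods
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  f <- blandAltman(x, y); g <- blandAltman(y, x)
  expect_equal(f$bias, -g$bias)
  expect_equal(f$loaLow, -g$loaHigh)
  expect_error(blandAltman(1, 1), "at least 2")
})

test_that("rmAnova matches the hand ANOVA decomposition on a 3 x 4 table", {
  areas <- matrix(c(0.50, 0.45, 0.42, 0.41,
                    0.60, 0.52, 0.50, 0.49,
                    0.40, 0.38, 0.36, 0.37), nrow = 3, byrow = TRUE)
  tab <- do.call(rbind, lapply(1:3, function(i) data.frame(
    subject_id = paste0("S", i), eye = "OD", visit = 1:4, plexus = "SVP",
    method = "script", pixel_count = 1L, area_mm2 = areas[i, ],
    stringsAsFactors = FALSE)))
  out <- rmAnova(tab, "SVP", "script")
  # hand decomposition
  grand <- mean(areas)
  ssVisit <- 3 * sum((colMeans(areas) - grand)^2)
  ssSubj <- 4 * sum((rowMeans(areas) - grand)^2)
  ssTot <- sum((areas - grand)^2)
  ssErr <- ssTot - ssVisit - ssSubj
  Fhand <- (ssVisit / 3) / (ssErr / 6)
  expect_equal(out$F, Fhand, tolerance = 1e-10)
  expect_equal(out$df1, 3)
  expect_equal(out$df2, 6)
  expect_equal(out$p, pf(Fhand, 3, 6, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(out$nComplete, 3)
})

test_that("identical visits give F ~ 0 and all-1 adjusted p-values", {
  tab <- do.call(rbind, lapply(1:5, function(i) data.frame(
    subject_id = paste0("S", i), eye = "OD", visit = 1:4, plexus = "SVP",
    method = "script", pixel_count = 1L, area_mm2 = 0.3 + 0.01 * i,
    stringsAsFactors = FALSE)))
  out <- rmAnova(tab, "SVP", "script")
  expect_lt(abs(out$F), 1e-8)
  pw <- tukeyPairwise(tab, "SVP", "script")
  expect_equal(nrow(pw), 6)   # C(4,2) pairs
  expect_true(all(pw$p_adj > 1 - 1e-6))
})

test_that("incomplete subjects are dropped as complete-case analysis", {
  set.seed(31)
  tab <- simulateAreaTable(6, c(0.5, 0.45, 0.42, 0.41))
  tab <- tab[!(tab$subject_id == "S006" & tab$visit == 3), ]
  out <- rmAnova(tab, "SVP", "script")
  expect_equal(out$nComplete, 5)
  expect_equal(out$nDropped, 1)
  tiny <- tab[tab$subject_id %in% c("S001", "S006"), ]
  expect_error(rmAnova(tiny, "SVP", "script"), "at least 2 subjects")
})

test_that("k = 2 Tukey p equals the paired t-test p", {
  set.seed(7)
  tab <- simulateAreaTable(12, c(0.5, 0.44))
  pw <- tukeyPairwise(tab, "SVP", "script")
  x1 <- tab$area_mm2[tab$visit == 1]
  x2 <- tab$area_mm2[tab$visit == 2]
  tt <- t.test(x1, x2, paired = TRUE)
  expect_equal(pw$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("tukeyPairwise agrees with TukeyHSD on the same model", {
  set.seed(13)
  tab <- simulateAreaTable(8, c(0.5, 0.47, 0.42, 0.41))
  pw <- tukeyPairwise(tab, "SVP", "script")
  fit <- aov(area_mm2 ~ factor(subject_id) + factor(visit), data = tab)
  th <- TukeyHSD(fit, "factor(visit)")$`factor(visit)`
  key <- paste(pw$visit_i, pw$visit_j, sep = "-")
  thKey <- sub("^(\\d)-(\\d)$", "\\2-\\1", rownames(th))
  ord <- match(key, thKey)
  expect_equal(pw$p_adj, unname(th[ord, "p adj"]), tolerance = 1e-8)
  expect_equal(abs(pw$diff), unname(abs(th[ord, "diff"])), tolerance = 1e-10)
})

test_that("studentized range CDF: limits and the k = 2 normal identity", {
  expect_equal(studentizedRangeCdf(0, 4, 10), 0)
  expect_gte(studentizedRangeCdf(50, 4, 30), 1 - 1e-9)
  # k = 2, large df: CDF(q) = 2 Phi(q / sqrt(2)) - 1
  q <- 1.96 * sqrt(2)
  expect_equal(studentizedRangeCdf(q, 2, 1e6), 0.95, tolerance = 1e-4)
  expect_error(studentizedRangeCdf(-1, 2, 10), ">= 0")
  expect_error(studentizedRangeCdf(1, 1, 10), "k")
  # monotone in q
  qs <- seq(0, 8, by = 0.5)
  expect_true(all(diff(studentizedRangeCdf(qs, 3, 20)) > 0))
})

test_that("statistics are invariant to record order", {
  set.seed(17)
  tab <- simulateAreaTable(10, c(0.5, 0.45, 0.42, 0.41))
  shuf <- tab[sample(nrow(tab)), ]
  a <- rmAnova(tab, "SVP", "script")
  b <- rmAnova(shuf, "SVP", "script")
  expect_equal(a$F, b$F, tolerance = 1e-12)
  expect_equal(tukeyPairwise(tab, "SVP", "script")$p_adj,
               tukeyPairwise(shuf, "SVP", "script")$p_adj, tolerance = 1e-12)
})

test_that("agreement report pairs methods within plexus pooling visits", {
  set.seed(23)
  s <- simulateAreaTable(10, c(0.5, 0.45, 0.42, 0.41), method = "script")
  m <- s
  m$method <- "ml"
  m$area_mm2 <- s$area_mm2 * 0.95 + rnorm(nrow(s), 0, 0.01)
  rep_ <- agreementReport(rbind(s, m), "SVP")
  expect_equal(rep_$n, 40)
  expect_gt(rep_$r, 0.9)
  expect_true(rep_$ciLow <= rep_$r && rep_$r <= rep_$ciHigh)
  expect_true(rep_$loaLow <= rep_$bias && rep_$bias <= rep_$loaHigh)
})

test_that("limits of agreement contain ~95% of normal differences", {
  set.seed(41)
  x <- rnorm(2000, 0.45, 0.1)
  y <- x - rnorm(2000, 0.01, 0.02)
  ba <- blandAltman(x, y)
  inside <- mean(ba$diffs >= ba$loaLow & ba$diffs <= ba$loaHigh)
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
  # flagged outliers and in-limits pairs partition the sample
  expect_equal(sort(c(ba$outliers,
    which(ba$diffs >= ba$loaLow & ba$diffs <= ba$loaHigh))), 1:2000)
})
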