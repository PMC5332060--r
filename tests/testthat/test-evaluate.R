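test_that("tissue names follow mean ADC ordering, not class indices", {
  shape <- c(6L, 1L, 1L)
  mask <- array(1L, dim = shape)
  labels <- array(c(1L, 1L, 2L, 2L, 3L, 3L), dim = shape)
  adc <- array(c(1250, 1250, 1130, 1130, 600, 600), dim = shape)
  seg <- fake_seg(labels, list(ADC = adc))
  expect_equal(seg$class_info$tissue, c("necrotic", "peri-necrotic", "viable"))
  # permuted class indices: names follow means
  seg2 <- fake_seg(array(c(3L, 3L, 1L, 1L, 2L, 2L), dim = shape),
                   list(ADC = adc))
  expect_equal(seg2$class_info$tissue[c(3, 1, 2)],
               c("necrotic", "peri-necrotic", "viable"))
  # K = 4: lowest-ADC surplus class becomes other_1
  labels4 <- array(c(1L, 2L, 2L, 3L, 4L, 4L), dim = shape)
  adc4 <- array(c(1250, 1130, 1130, 600, 590, 590), dim = shape)
  seg4 <- fake_seg(labels4, list(ADC = adc4))
  expect_equal(seg4$class_info$tissue, c("necrotic", "peri-necrotic",
                                         "viable", "other_1"))
  # K < 3 is an error
  seg2c <- fake_seg(array(c(1L, 1L, 1L, 2L, 2L, 2L), dim = shape),
                    list(ADC = adc), K = 2)
  expect_error(assign_tissue_names(seg2c), ">=3 classes")
})

test_that("fractions count voxels (hard) or average probabilities (soft)", {
  shape <- c(10L, 1L, 1L)
  labels <- array(c(rep(1L, 4), rep(2L, 3), rep(3L, 3)), dim = shape)
  adc <- array(seq(1000, 100, length.out = 10), dim = shape)
  seg <- fake_seg(labels, list(ADC = adc))
  f <- compute_fractions(seg, "hard")
  expect_equal(unname(f$fractions[order(names(f$fractions))]),
               c(0.4, 0.3, 0.3)[order(seg$class_info$tissue)])
  expect_equal(sum(f$fractions), 1, tolerance = 1e-12)
  # soft on a one-hot field equals hard
  fs <- compute_fractions(seg, "soft")
  expect_equal(fs$fractions, f$fractions)
  # all one class
  seg1 <- fake_seg(array(1L, dim = shape), list(ADC = adc), K = 1)
  expect_equal(unname(compute_fractions(seg1)$fractions), 1)
})

test_that("match_labels finds the optimal permutation and sane ARI", {
  truth <- withr::with_seed(40, sample(1:3, 200, replace = TRUE))
  perm <- c(3L, 1L, 2L)
  pred <- perm[truth]
  mm <- match_labels(pred, truth)
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$ari, 1)
  expect_equal(unname(mm$dice), rep(1, 3))
  # independent labels: ARI near zero
  a <- withr::with_seed(41, sample(1:3, 5000, replace = TRUE))
  b <- withr::with_seed(42, sample(1:3, 5000, replace = TRUE))
  expect_lt(abs(match_labels(a, b)$ari), 0.05)
  # printed confusion counts vs exhaustive search over all 6 permutations
  C <- rbind(c(30, 5, 2), c(4, 20, 6), c(1, 3, 25))
  t3 <- rep(1:3, rowSums(C))
  p3 <- unlist(lapply(1:3, function(i) rep(1:3, C[i, ])))
  mm3 <- match_labels(p3, t3)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- max(vapply(perms, function(s) sum(C[cbind(1:3, s)]), numeric(1)))
  expect_equal(mm3$accuracy, best / sum(C))
  # invariance to relabeling of either argument
  mm4 <- match_labels(c(3L, 1L, 2L)[p3], c(2L, 3L, 1L)[t3])
  expect_equal(mm4$accuracy, mm3$accuracy)
  expect_equal(mm4$ari, mm3$ari)
  # differing class counts: leftover classes reported
  mm5 <- match_labels(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 3L))
  expect_length(mm5$unmatched, 1L)
})

test_that("correlate_fractions matches the textbook formula and edge cases", {
  mkfrac <- function(v) stats::setNames(v, c("necrotic", "peri-necrotic",
                                             "viable"))
  ref <- lapply(1:5, function(s) mkfrac(c(0.2, 0.3, 0.5) + (s - 3) * 0.02))
  expect_equal(correlate_fractions(ref, ref)$r, rep(1, 4))
  neg <- lapply(ref, function(f) mkfrac(-2 * f + 1))
  expect_equal(correlate_fractions(neg, ref)$r, rep(-1, 4))
  # brute-force covariance formula on given vectors
  x <- c(0.1, 0.4, 0.5, 0.2, 0.7); y <- c(0.2, 0.5, 0.4, 0.2, 0.8)
  px <- lapply(seq_along(x), function(i) c(t = x[i]))
  py <- lapply(seq_along(y), function(i) c(t = y[i]))
  r <- correlate_fractions(px, py)$r[1]
  rref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, rref, tolerance = 1e-12)
  # affine invariance under common positive rescaling
  sx <- lapply(px, function(v) v * 3 + 0.1)
  sy <- lapply(py, function(v) v * 3 + 0.1)
  expect_equal(correlate_fractions(sx, sy)$r[1], r, tolerance = 1e-12)
  # zero variance reported as undefined, not NaN
  z <- lapply(1:4, function(i) c(t = 0.5))
  out <- correlate_fractions(z, py[1:4])
  expect_true(is.na(out$r[1]))
  expect_match(out$note[1], "zero variance")
  # < 3 subjects per tissue
  out2 <- correlate_fractions(px[1:2], py[1:2])
  expect_match(out2$note[1], "fewer than 3")
})

test_that("adding an empty class leaves other fractions unchanged", {
  shape <- c(10L, 1L, 1L)
  labels <- array(c(rep(1L, 6), rep(2L, 4)), dim = shape)
  adc <- array(1:10 * 100, dim = shape)
  f2 <- compute_fractions(fake_seg(labels, list(ADC = adc), K = 2))
  f3 <- compute_fractions(fake_seg(labels, list(ADC = adc), K = 3))
  expect_equal(unname(f3$fractions[1:2]), unname(f2$fractions))
  expect_equal(unname(f3$fractions[3]), 0)
})

test_that("classwise statistics flag overwhelming separation, respect alpha", {
  shape <- c(600L, 1L, 1L)
  labels <- array(rep(1:3, each = 200), dim = shape)
  vals <- withr::with_seed(43, c(rnorm(200, 0), rnorm(200, 5), rnorm(200, 10)))
  maps <- list(ADC = array(rank(-vals) , dim = shape),  # ADC orders classes
               T2_pre = array(vals, dim = shape))
  seg <- fake_seg(labels, maps)
  st <- classwise_parameter_stats(seg, mp_stack(maps, array(1L, dim = shape)))
  expect_equal(st$alpha, 0.05 / 3)
  pw <- st$pairwise[st$pairwise$parameter == "T2_pre", ]
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$significant))
  # summary carries box-plot quantities per class
  sm <- st$summary[st$summary$parameter == "T2_pre", ]
  expect_equal(nrow(sm), 3L)
  one <- vals[1:200]
  expect_equal(sm$p5[sm$tissue == sm$tissue[which.max(sm$n)] ][1],
               unname(quantile(one, 0.05)), tolerance = 10)  # sanity scale
  expect_true(all(c("mean", "sd", "median", "p5", "p95", "ks_p") %in%
                    names(sm)))
  # classes with < 2 voxels are skipped and flagged
  lab2 <- array(c(rep(1L, 598), 2L, 3L), dim = shape)
  seg2 <- fake_seg(lab2, maps)
  st2 <- classwise_parameter_stats(seg2,
                                   mp_stack(maps, array(1L, dim = shape)))
  expect_length(st2$skipped, 2L)
})
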