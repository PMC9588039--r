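test_that("deterministic quantile normalization maps ranks to normal quantiles", {
  out <- quantile_normalize(c(10, 30, 20))
  expect_equal(out, c(qnorm(1 / 6), qnorm(5 / 6), qnorm(0.5)), tolerance = 1e-3)
  expect_equal(out[3], 0, tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(57, 100, 15)
  expect_equal(cor(x, quantile_normalize(x), method = "spearman"), 1)
  expect_error(quantile_normalize(5), "at least 2")
})

test_that("sampled quantile normalization keeps ranks but varies with seed", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  a <- quantile_normalize(x, "sampled", seed = 1)
  b <- quantile_normalize(x, "sampled", seed = 2)
  expect_equal(rank(a), rank(x))
  expect_equal(rank(b), rank(x))
  expect_false(identical(a, b))
})

test_that("normalized scores are near standard normal for moderate n", {
  x <- runif(250, 50, 150)
  q <- quantile_normalize(x)
  expect_lt(abs(mean(q)), 0.05)
  expect_lt(abs(sd(q) - 1), 0.05)
})

test_that("augmentation with zero probability is the identity", {
  st <- tiny_study()
  cfg <- gcnn_train_config(p_augment = 0)
  rec <- st$cohort[[1]]
  set.seed(1)
  out <- augment_meshes(rec, cfg)
  expect_identical(out$meshes, rec$meshes)
})

test_that("rotation-only augmentation preserves pairwise distances", {
  st <- tiny_study()
  cfg <- gcnn_train_config(p_augment = 1, noise_sigma = 0)
  mesh <- st$cohort[[2]]$meshes[["cortex_inner.left"]]
  set.seed(3)
  out <- augment_meshes(list(mesh), cfg)[[1]]
  d0 <- dist(mesh$vertices[1:40, ])
  d1 <- dist(out$vertices[1:40, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_gt(max(abs(out$vertices - mesh$vertices)), 1e-4)  # actually rotated
})

test_that("coordinate noise has the configured standard deviation", {
  cfg <- gcnn_train_config(p_augment = 1, rotation_limit_deg = 0,
                           noise_sigma = 0.02)
  v <- matrix(0, 33400, 3)                  # ~1e5 coordinates
  f <- cbind(1:33398, 2:33399, 3:33400)
  m <- surface_mesh(v + runif(length(v)), f, "thalamus", "left")
  set.seed(11)
  out <- augment_meshes(list(m), cfg)[[1]]
  sd_emp <- sd(out$vertices - m$vertices)
  expect_lt(abs(sd_emp - 0.02) / 0.02, 0.02)
})

test_that("the loss decomposes into MSE, l2 and correlation terms", {
  l <- compute_loss(c(1, 2), c(1.5, 2.5), NULL, 0, 0)
  expect_equal(l$total, 0.25, tolerance = 1e-10)
  expect_equal(l$total, l$mse_term)
  ## perfect prediction with only the correlation reward
  l2 <- compute_loss(c(1, 2, 3), c(1, 2, 3), NULL, 0, 1)
  expect_equal(l2$total, -1, tolerance = 1e-10)
  expect_equal(l2$corr_term, 1)
  ## zero-variance guard
  l3 <- compute_loss(c(0, 0), c(1, -1), NULL, 0, 1)
  expect_equal(l3$corr_term, 0)
  expect_equal(l3$total, 1, tolerance = 1e-10)
  ## weights enter through the l2 term
  l4 <- compute_loss(c(0, 0), c(0, 0), c(2, -3), lambda1 = 0.1, lambda2 = 0)
  expect_equal(l4$reg_term, 13)
  expect_equal(l4$total, 1.3, tolerance = 1e-10)
  expect_error(compute_loss(1:3, 1:2), "length")
})

test_that("the total always equals mse + l1*reg - l2*corr", {
  set.seed(4)
  for (i in 1:10) {
    yp <- rnorm(8); yt <- rnorm(8); w <- rnorm(5)
    l <- compute_loss(yp, yt, w, 0.3, 0.7)
    expect_equal(l$total, l$mse_term + 0.3 * l$reg_term - 0.7 * l$corr_term,
                 tolerance = 1e-10)
    expect_gte(l$corr_term, -1); expect_lte(l$corr_term, 1)
  }
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(6)
  yp <- rnorm(12); yt <- rnorm(12)
  g <- surfgcnn:::loss_pred_grad(yp, yt, lambda2 = 0.8)
  eps <- 1e-7
  for (i in c(1, 5, 12)) {
    up <- yp; up[i] <- up[i] + eps
    dn <- yp; dn[i] <- dn[i] - eps
    fd <- (compute_loss(up, yt, NULL, 0, 0.8)$total -
             compute_loss(dn, yt, NULL, 0, 0.8)$total) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-6)
  }
})

test_that("fold sizes reproduce the two cohort layouts", {
  s1 <- make_nested_splits(paste0("a", 1:8070), 6, 5, seed = 1)
  expect_equal(unname(table(s1$outer_assignment)), rep(1345L, 6L),
               ignore_attr = TRUE)
  s2 <- make_nested_splits(paste0("h", 1:1097), 6, 5, seed = 1)
  sizes <- as.integer(table(s2$outer_assignment))
  expect_equal(max(sizes), 183L)
  expect_equal(1097L - max(sizes), 914L)
  expect_equal(sort(unique(sizes)), c(182L, 183L))
  s3 <- make_nested_splits(paste0("x", 1:12), 6, 5, seed = 1)
  expect_equal(as.integer(table(s3$outer_assignment)), rep(2L, 6L))
  expect_error(make_nested_splits(paste0("x", 1:5), 6), "cannot fill")
})

test_that("nested folds never leak across train, validation and test sets", {
  ids <- paste0("s", 1:47)
  for (seed in 1:200) {
    sp <- make_nested_splits(ids, 6, 5, seed = seed)
    expect_setequal(names(sp$outer_assignment), ids)
    for (of in 1:6) {
      test_ids <- ids[sp$outer_assignment == of]
      inner <- sp$inner_assignment[[of]]
      expect_setequal(names(inner), setdiff(ids, test_ids))
      expect_length(intersect(names(inner), test_ids), 0L)
      expect_equal(sort(unique(as.integer(inner))), 1:5)
    }
  }
})

test_that("a zero learning rate leaves parameters untouched", {
  st <- tiny_study()
  tc <- gcnn_train_config(batch_size = 8, max_epochs = 3, learning_rate = 0,
                          p_augment = 0, patience = 5, seed = 1)
  mc <- gcnn_model_config(9L, channels = c(4L, 4L, 6L, 6L), dropout_rate = 0,
                          seed = 9)
  m0 <- build_model(mc, st$dataset$hierarchy)
  res <- surfgcnn:::train_gcnn(st$dataset, 1:16, 17:20, mc, tc)
  expect_equal(res$model$params, m0$params, tolerance = 1e-14)
})

test_that("training halts at patience + 1 epochs when validation never improves", {
  st <- tiny_study()
  ## lr = 0 keeps validation MSE exactly constant: the first epoch sets the
  ## best value and every later epoch counts toward patience
  tc <- gcnn_train_config(batch_size = 8, max_epochs = 20, learning_rate = 0,
                          p_augment = 0, patience = 3, seed = 1)
  mc <- gcnn_model_config(9L, channels = c(4L, 4L, 6L, 6L), dropout_rate = 0,
                          seed = 9)
  res <- surfgcnn:::train_gcnn(st$dataset, 1:16, 17:20, mc, tc)
  expect_equal(nrow(res$history), 4L)
})

test_that("a tiny network overfits a 16-subject training set", {
  st <- tiny_study()
  ## pure squared-error objective: memorizing 16 subjects must at least
  ## halve the training MSE
  tc <- gcnn_train_config(batch_size = 8, max_epochs = 150,
                          learning_rate = 2e-3, lambda1 = 0, lambda2 = 0,
                          p_augment = 0, patience = 150, seed = 2)
  mc <- gcnn_model_config(9L, channels = c(4L, 4L, 6L, 6L), dropout_rate = 0,
                          seed = 2)
  res <- surfgcnn:::train_gcnn(st$dataset, 1:16, integer(0), mc, tc)
  h <- res$history
  expect_lt(min(h$train_mse), 0.5 * h$train_mse[1])
  expect_lt(tail(h$train_mse, 1), h$train_mse[1])
})

test_that("ensembling averages member predictions", {
  st <- tiny_study()
  m1 <- tiny_model(seed = 1)
  m2 <- tiny_model(seed = 2)
  x <- st$dataset$padded[, , 1:5]
  p1 <- forward(m1, x)$pred
  p2 <- forward(m2, x)$pred
  ens <- ensemble_predict(list(m1, m2), x)
  expect_equal(ens, (p1 + p2) / 2, tolerance = 1e-12)
  expect_equal(ensemble_predict(list(m1, m1, m1), x), p1, tolerance = 1e-12)
  ## members with different configurations are rejected
  m3 <- build_model(gcnn_model_config(9L, channels = c(5L, 4L, 6L, 6L),
                                      seed = 1), st$dataset$hierarchy)
  expect_error(ensemble_predict(list(m1, m3), x), "differ")
})

test_that("prediction averaging never exceeds the members' mean MSE", {
  set.seed(12)
  for (trial in 1:50) {
    yt <- rnorm(20)
    members <- replicate(5, yt + rnorm(20, sd = runif(1, 0.1, 2)))
    ens <- rowMeans(members)
    member_mse <- mean(apply(members, 2, function(p) mean((p - yt)^2)))
    expect_lte(mean((ens - yt)^2), member_mse + 1e-12)
  }
})

test_that("evaluation metrics cover the exact and anti-correlated cases", {
  m1 <- evaluate_predictions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(m1$mse, 0)
  expect_equal(m1$r, 1)
  m2 <- evaluate_predictions(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(m2$mse, 1)
  expect_equal(m2$r, 1)
  m3 <- evaluate_predictions(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(m3$r, -1)
  expect_true(m3$r_ci[1] <= m3$r & m3$r <= m3$r_ci[2])
  m4 <- evaluate_predictions(rep(1, 5), rnorm(5))
  expect_true(m4$degenerate)
  expect_error(evaluate_predictions(1:2, 1:2), "at least 3")
})

test_that("confidence and prediction intervals are ordered and calibrated", {
  set.seed(30)
  yp <- rnorm(100)
  yt <- yp * 0.5 + rnorm(100, sd = 0.5)
  m <- evaluate_predictions(yp, yt)
  expect_lt(m$r_ci[1], m$r)
  expect_gt(m$r_ci[2], m$r)
  expect_lt(m$pi[1], m$pi[2])
  ## the prediction interval at the mean covers most observations near it
  expect_gt(m$pi[2] - m$pi[1], 2 * sd(yt - yp * coef(lm(yt ~ yp))[2]))
})

test_that("model comparison applies the Benjamini-Hochberg step-up", {
  ## worked example: raw p (0.01, 0.02, 0.03) -> adjusted all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(2)
  base <- runif(6, 0.2, 0.5)
  r <- list(all = base + 0.05 + rnorm(6, sd = 0.01),
            cor = base,
            sub = base - 0.1 + rnorm(6, sd = 0.01))
  out <- compare_models(r)
  expect_equal(nrow(out), 3L)
  expect_equal(out$p_adj, p.adjust(out$p, "BH"))
  ## identical paired samples give t = 0, p = 1
  out2 <- compare_models(list(a = base, b = base))
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  expect_equal(out2$p_adj, out2$p)        # single comparison unchanged
  expect_error(compare_models(list(a = 1:3, b = 1:4)), "paired")
})

test_that("train_fold produces one early-stopped model per inner fold", {
  st <- tiny_study()
  split <- make_nested_splits(st$dataset$subject_ids, outer_k = 4L,
                              inner_k = 2L, seed = 3)
  tc <- gcnn_train_config(batch_size = 8, max_epochs = 2, learning_rate = 1e-3,
                          p_augment = 0, patience = 2, seed = 1)
  mc <- gcnn_model_config(9L, channels = c(4L, 4L, 6L, 6L), dropout_rate = 0,
                          seed = 1)
  fold <- train_fold(st$dataset, split, 1L, mc, tc)
  expect_length(fold$models, 2L)
  expect_length(fold$logs, 2L)
  expect_true(all(vapply(fold$logs, nrow, 0L) <= 2L))
  ## inner-fold models differ (different training subsets and seeds)
  expect_false(identical(fold$models[[1]]$params, fold$models[[2]]$params))
})
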