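raw_fit <- function(scores) {
  r <- unclass(scores) + attr(scores, "provenance")$shift
  array(as.numeric(r), dim(r))
}

test_that("cf_scores is the similarity-weighted neighborhood average", {
  net <- lmi_network(c("L1", "L2"), c("M1", "M2"), rbind(c(0, 0), c(1, 1)))
  sim <- prepare_similarity(matrix(1, 2, 2))
  s <- cf_scores(net, sim, "lnc", quiet = TRUE)
  expect_equal(s["L1", "M1"], 1)  # single neighbor with sim 1 and an edge

  # hand-computed 3 x 2 instance
  net3 <- lmi_network(paste0("L", 1:3), paste0("M", 1:2),
                      rbind(c(1, 0), c(0, 1), c(1, 1)))
  S <- rbind(c(1, 0.2, 0.8), c(0.2, 1, 0.4), c(0.8, 0.4, 1))
  s3 <- cf_scores(net3, prepare_similarity(S), "lnc", quiet = TRUE)
  for (a in 1:3) for (b in 1:2) {
    others <- setdiff(1:3, a)
    expect_equal(s3[a, b],
                 sum(S[a, others] * net3$A[others, b]) / sum(S[a, others]))
  }
  # miRNA side is the symmetric construction
  Sm <- rbind(c(1, 0.6), c(0.6, 1))
  s3m <- cf_scores(net3, prepare_similarity(Sm), "mir", quiet = TRUE)
  for (a in 1:3) for (b in 1:2) {
    o <- setdiff(1:2, b)
    expect_equal(s3m[a, b], sum(net3$A[a, o] * Sm[o, b]) / sum(Sm[o, b]))
  }

  # all-zero off-diagonal similarity: zero scores, logged
  zs <- prepare_similarity(matrix(0, 3, 3))
  expect_message(z <- cf_scores(net3, zs, "lnc"), "zero neighborhood")
  expect_true(all(z == 0))
  expect_error(cf_scores(net3, prepare_similarity(diag(2)), "lnc"), "side")
})

test_that("svd_scores reconstructs A at full rank and matches an eigen oracle", {
  net <- lmi_network(paste0("L", 1:5), paste0("M", 1:4),
                     rbind(c(1, 0, 1, 0), c(0, 1, 0, 0), c(1, 1, 1, 0),
                           c(0, 0, 0, 1), c(1, 0, 0, 1)))
  full <- svd_scores(net, rank = 4)
  expect_equal(unname(raw_fit(full)), unname(net$A), tolerance = 1e-9)
  expect_true(all(full >= 0))

  # rank-1 reconstruction of a rank-1 A is exact
  r1 <- lmi_network(paste0("L", 1:3), paste0("M", 1:3),
                    outer(c(1, 1, 0), c(1, 0, 1)))
  expect_equal(unname(raw_fit(svd_scores(r1, rank = 1))), unname(r1$A),
               tolerance = 1e-9)

  # rank-2 truncation matches an independent eigendecomposition of A^T A
  set.seed(20)
  net2 <- random_network(5, 4, 0.5)
  eig <- eigen(crossprod(net2$A), symmetric = TRUE)
  V <- eig$vectors[, 1:2, drop = FALSE]
  rec2 <- (net2$A %*% V) %*% t(V)
  expect_equal(unname(raw_fit(svd_scores(net2, rank = 2))), unname(rec2),
               tolerance = 1e-8)
  expect_error(svd_scores(net2, rank = 0), "rank")
  expect_error(svd_scores(net2, rank = 9), "rank")
})

test_that("lfm loss is non-increasing and fits are seed-deterministic", {
  set.seed(21)
  net <- random_network(6, 4, 0.4)
  s <- lfm_scores(net, factors = 2, epochs = 150, seed = 5)
  expect_true(all(diff(attr(s, "loss")) < 1e-6))
  s2 <- lfm_scores(net, factors = 2, epochs = 150, seed = 5)
  expect_identical(unclass(s), unclass(s2))
  s3 <- lfm_scores(net, factors = 2, epochs = 150, seed = 6)
  expect_false(identical(unclass(s), unclass(s3)))
})

test_that("lfm recovers a noiseless rank-2 adjacency to < 0.05 RMSE", {
  A <- outer(rep(c(1, 0), each = 4), rep(c(1, 0), each = 3)) +
       outer(rep(c(0, 1), each = 4), rep(c(0, 1), each = 3))
  net <- lmi_network(paste0("L", 1:8), paste0("M", 1:6), A)
  s <- lfm_scores(net, factors = 2, epochs = 500, lr = 0.02, reg = 1e-4,
                  seed = 7)
  expect_lt(sqrt(mean((raw_fit(s) - A)^2)), 0.05)
})

test_that("katz_scores follows the walk expansion", {
  net <- lmi_network(c("L1", "L2"), c("M1", "M2"), rbind(c(1, 0), c(0, 1)))
  LS <- prepare_similarity(rbind(c(1, 0.5), c(0.5, 1)))
  MS <- prepare_similarity(rbind(c(1, 0.3), c(0.3, 1)))
  b <- 0.01
  k1 <- katz_scores(net, LS, MS, beta = b, kmax = 1)
  expect_equal(unname(unclass(k1)), b * unname(net$A), tolerance = 1e-12,
               ignore_attr = TRUE)
  k2 <- katz_scores(net, LS, MS, beta = b, kmax = 2)
  LS0 <- unclass(LS); diag(LS0) <- 0
  MS0 <- unclass(MS); diag(MS0) <- 0
  expect_equal(unname(unclass(k2)),
               unname(b * net$A + b^2 * (LS0 %*% net$A + net$A %*% MS0)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(katz_scores(net, LS, MS, kmax = 0), "kmax")
  expect_warning(katz_scores(net, LS, MS, beta = 2, kmax = 2), "spectral")

  # extending kmax changes scores by at most (beta ||M||)^(kmax+1)
  set.seed(23)
  net2 <- random_network(4, 3, 0.5)
  LS2 <- random_prepared_sim(4, net2$lnc_ids)
  MS2 <- random_prepared_sim(3, net2$mir_ids)
  LS20 <- unclass(LS2); diag(LS20) <- 0
  MS20 <- unclass(MS2); diag(MS20) <- 0
  M <- rbind(cbind(LS20, net2$A), cbind(t(net2$A), MS20))
  for (km in 2:4) {
    d <- max(abs(suppressWarnings(katz_scores(net2, LS2, MS2, 0.05, km + 1)) -
                 suppressWarnings(katz_scores(net2, LS2, MS2, 0.05, km))))
    expect_lte(d, 0.05^(km + 1) * norm(M, "2")^(km + 1) + 1e-12)
  }
})

test_that("baselines are permutation-equivariant", {
  set.seed(24)
  net <- random_network(5, 4, 0.5)
  LS <- random_prepared_sim(5, net$lnc_ids)
  MS <- random_prepared_sim(4, net$mir_ids)
  pl <- sample(5); pm <- sample(4)
  net_p <- lmi_network(net$lnc_ids[pl], net$mir_ids[pm], net$A[pl, pm])
  LS_p <- prepare_similarity(unclass(LS)[pl, pl])
  MS_p <- prepare_similarity(unclass(MS)[pm, pm])
  for (meth in c("cf_lnc", "cf_mir", "svd", "katz")) {
    params <- list(rank = 2L, kmax = 3L, seed = 3L)
    f <- lmi_method(meth, LS, MS, params)
    f_p <- lmi_method(meth, LS_p, MS_p, params)
    expect_equal(unclass(f_p(net_p)), unclass(f(net))[pl, pm],
                 tolerance = 1e-8, ignore_attr = TRUE,
                 label = paste("equivariance", meth))
  }
})
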