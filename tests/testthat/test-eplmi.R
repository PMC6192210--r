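prep <- function(M) prepare_similarity(M)

test_that("weighted_networks applies the similarity product and epsilon rule", {
  net <- lmi_network(c("L1", "L2"), c("M1", "M2"), diag(2))
  LS <- prep(rbind(c(1, 0.5), c(0.5, 1)))
  MS <- prep(diag(2))
  pair <- weighted_networks(net, LS, MS)
  expect_equal(unname(pair$A_l), rbind(c(1, 0.5), c(0.5, 1)))
  # MS = identity: A_m = A with zeros replaced by epsilon
  expect_equal(unname(pair$A_m), rbind(c(1, 1e-11), c(1e-11, 1)))
  expect_true(all(pair$A_l > 0) && all(pair$A_m > 0))
  expect_error(weighted_networks(net, LS, MS, epsilon = 0), "epsilon")
  expect_error(weighted_networks(net, prep(diag(3)), MS), "LS")
  expect_error(weighted_networks(net, unclass(diag(2)), MS), "prepared")
})

test_that("forward_resources normalizes columns of C and rows of R", {
  W <- rbind(c(1, 1), c(1, 3))
  res <- forward_resources(W)
  expect_equal(unname(res$C), rbind(c(0.5, 0.25), c(0.5, 0.75)))
  expect_equal(unname(res$R), rbind(c(0.5, 0.5), c(0.25, 0.75)))
  # constant W: uniform shares
  resc <- forward_resources(matrix(2, 3, 4))
  expect_true(all(abs(resc$C - 1 / 3) < 1e-12))
  expect_true(all(abs(resc$R - 1 / 4) < 1e-12))
  expect_error(forward_resources(rbind(c(1, 0), c(1, 1))), "positive")
  set.seed(2)
  W2 <- matrix(runif(30) + 0.01, 5, 6)
  res2 <- forward_resources(W2)
  expect_equal(unname(colSums(res2$C)), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(rowSums(res2$R)), rep(1, 5), tolerance = 1e-9)
})

test_that("identity-similarity limit returns the adjacency for matched pairs", {
  net <- lmi_network(c("L1", "L2"), c("M1", "M2"), diag(2))
  SS <- eplmi_scores(net, prep(diag(2)), prep(diag(2)))
  expect_true(max(abs(SS - net$A)) < 1e-9)
})

test_that("diffusion matches the path-enumeration oracle on random instances", {
  set.seed(10)
  for (i in 1:25) {
    nl <- sample(2:5, 1); nm <- sample(2:5, 1)
    net <- random_network(nl, nm)
    LS <- random_prepared_sim(nl, net$lnc_ids)
    MS <- random_prepared_sim(nm, net$mir_ids)
    SS <- eplmi_scores(net, LS, MS)
    expect_equal(unname(unclass(SS)),
                 diffusion_oracle(net$A, unclass(LS), unclass(MS)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("each propagation side conserves the column/row sums of A", {
  set.seed(11)
  net <- random_network(4, 3)
  LS <- random_prepared_sim(4, net$lnc_ids)
  MS <- random_prepared_sim(3, net$mir_ids)
  pair <- weighted_networks(net, LS, MS)
  for (W in list(pair$A_l, pair$A_m)) {
    res <- forward_resources(W)
    SS_lnc <- (res$C %*% t(res$R)) %*% net$A
    SS_mir <- net$A %*% crossprod(res$C, res$R)
    expect_equal(colSums(SS_lnc), colSums(net$A), tolerance = 1e-9)
    expect_equal(rowSums(SS_mir), rowSums(net$A), tolerance = 1e-9)
  }
  SS <- two_way_diffusion(net, pair)
  expect_equal(sum(SS), sum(net$A), tolerance = 1e-9)
})

test_that("scores are equivariant under simultaneous relabeling", {
  set.seed(12)
  net <- random_network(5, 4)
  LS <- random_prepared_sim(5, net$lnc_ids)
  MS <- random_prepared_sim(4, net$mir_ids)
  SS <- eplmi_scores(net, LS, MS)
  pl <- sample(5); pm <- sample(4)
  net_p <- lmi_network(net$lnc_ids[pl], net$mir_ids[pm], net$A[pl, pm])
  LS_p <- prepare_similarity(unclass(LS)[pl, pl])
  MS_p <- prepare_similarity(unclass(MS)[pm, pm])
  SS_p <- eplmi_scores(net_p, LS_p, MS_p)
  expect_equal(unclass(SS_p), unclass(SS)[pl, pm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("raising the similarity to an interacting lncRNA never lowers a score", {
  set.seed(13)
  for (rep in 1:10) {
    net <- random_network(4, 3, p = 0.5)
    LSm <- unclass(random_prepared_sim(4, net$lnc_ids))
    MS <- random_prepared_sim(3, net$mir_ids)
    b <- sample(which(colSums(net$A) > 0), 1)
    l <- sample(which(net$A[, b] == 1), 1)
    a <- sample(setdiff(seq_len(4), l), 1)
    base <- eplmi_scores(net, prepare_similarity(LSm), MS)[a, b]
    LSm2 <- LSm
    LSm2[a, l] <- LSm2[l, a] <- min(1, LSm[a, l] + 0.3)
    up <- eplmi_scores(net, prepare_similarity(LSm2), MS)[a, b]
    expect_gte(up, base - 1e-9)
  }
})

test_that("scores are stable as epsilon varies over [1e-12, 1e-10]", {
  set.seed(14)
  net <- random_network(6, 5, p = 0.6)
  LS <- random_prepared_sim(6, net$lnc_ids)
  MS <- random_prepared_sim(5, net$mir_ids)
  SS1 <- eplmi_scores(net, LS, MS, epsilon = 1e-12)
  SS2 <- eplmi_scores(net, LS, MS, epsilon = 1e-10)
  expect_lt(max(abs(SS1 - SS2)), 1e-6)
})

test_that("held-out within-block pairs outscore between-block pairs", {
  diffs <- vapply(1:20, function(seed) {
    ds <- degrade_dataset(generate_dataset(seed = seed), 0.2, seed = seed)
    sims <- dataset_sims(ds)
    SS <- eplmi_scores(ds$network, sims$LS, sims$MS)
    same <- outer(ds$lnc_blocks, ds$mir_blocks, "==")
    held_in <- ds$removed[same[ds$removed], , drop = FALSE]
    between <- which(ds$network$A == 0 & !same, arr.ind = TRUE)
    mean(SS[held_in]) - mean(SS[between])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})
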