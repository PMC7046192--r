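test_that("distance matrices match the site-by-site oracle and permute consistently", {
  expect_equal(max(distance_matrix(matrix(0L, 10, 3))), 0)
  set.seed(4)
  H <- matrix(sample(c(0L, 1L, NA), 4 * 60, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)), ncol = 4,
              dimnames = list(NULL, letters[1:4]))
  D <- distance_matrix(H, max_missing = 1)
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- !is.na(H[, i]) & !is.na(H[, j])
    expect_equal(D[i, j], sum(H[ok, i] != H[ok, j]) / sum(ok))
  }
  expect_equal(D, t(D))
  perm <- c(3, 1, 4, 2)
  D2 <- distance_matrix(H[, perm], max_missing = 1)
  expect_equal(D2, D[perm, perm])
  # mutation-set input equals matrix input over the union of positions
  sets <- list(a = c(1, 5, 9), b = c(5, 9, 12), c = numeric(0))
  Ds <- distance_matrix(sets)
  expect_equal(Ds["a", "b"], 2 / 4)
  expect_equal(Ds["a", "c"], 3 / 4)
  # a pair with no complete site errors naming the pair
  Hbad <- cbind(a = c(1L, NA, NA), b = c(NA, 1L, NA), c = c(1L, 1L, 0L))
  expect_error(distance_matrix(Hbad, max_missing = 1), "'a' and 'b'")
})

test_that("neighbor joining recovers an additive four-taxon tree", {
  # additive distances on ((a,b),(c,d)) with internal branch 3
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["c", "d"] <- D["d", "c"] <- 5
  D["a", "c"] <- D["c", "a"] <- 1 + 3 + 2
  D["a", "d"] <- D["d", "a"] <- 1 + 3 + 3
  D["b", "c"] <- D["c", "b"] <- 2 + 3 + 2
  D["b", "d"] <- D["d", "b"] <- 2 + 3 + 3
  nw <- nj_tree(D)
  tr <- ape::read.tree(text = nw)
  expect_setequal(tr$tip.label, letters[1:4])
  # the split {a,b} | {c,d} must be present
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  expect_true(any(vapply(splits, identical, logical(1), y = c("a", "b"))) ||
                any(vapply(splits, identical, logical(1), y = c("c", "d"))))
  # branch lengths reproduce the additive metric exactly
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[letters[1:4],
                                                           letters[1:4]]),
               unname(D), tolerance = 1e-10)
  # three taxa give the unique unrooted topology
  tr3 <- ape::read.tree(text = nj_tree(D[1:3, 1:3]))
  expect_equal(ape::Ntip(tr3), 3)
  Dbad <- D; Dbad[1, 2] <- Dbad[2, 1] <- NA
  expect_error(nj_tree(Dbad), "non-finite")
})

test_that("principal coordinates reproduce Euclidean distances", {
  set.seed(9)
  pts <- matrix(rnorm(6 * 3), ncol = 3)
  D <- as.matrix(dist(pts))
  emb <- pcoa_embed(D)
  expect_false(attr(emb, "corrected"))
  expect_equal(as.matrix(dist(emb)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalue sum equals the Gower trace
  n <- nrow(D)
  G <- -0.5 * (diag(n) - 1 / n) %*% (D^2) %*% (diag(n) - 1 / n)
  expect_equal(sum(attr(emb, "eig")), sum(diag(G)), tolerance = 1e-8)
  # zero matrix -> zero coordinates
  expect_true(all(pcoa_embed(matrix(0, 4, 4)) == 0))
  # non-Euclidean mismatch matrices get the Cailliez correction
  ch <- smoke_cohort()
  carriers <- carriers_of(ch)[1:6]
  Dm <- distance_matrix(lapply(stats::setNames(carriers, carriers),
                               function(s) ch$truth$haps[[s]]$auto$mat))
  emb2 <- pcoa_embed(Dm)
  expect_true(is.matrix(emb2))
})

test_that("m2 is invariant to rigid motions and rescaling of either matrix", {
  set.seed(12)
  X <- matrix(rnorm(8 * 7), 8)
  Y <- matrix(rnorm(8 * 7), 8)
  m0 <- neowsweep:::procrustes_m2(X, Y)
  expect_equal(neowsweep:::procrustes_m2(X * 13, Y), m0, tolerance = 1e-12)
  expect_equal(neowsweep:::procrustes_m2(X, Y * 0.02), m0, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(rnorm(49), 7)))
  expect_equal(neowsweep:::procrustes_m2(X %*% Q, Y), m0, tolerance = 1e-10)
  shift <- matrix(5, 8, 7)
  expect_equal(neowsweep:::procrustes_m2(X + shift, Y), m0, tolerance = 1e-10)
  # cross-check against the established Procrustes implementation
  ve <- vegan::procrustes(X, Y, symmetric = TRUE)
  expect_equal(m0, ve$ss, tolerance = 1e-8)
})

test_that("a parasite matrix identical to the host gives the smallest p", {
  set.seed(2)
  H <- matrix(sample(0:1, 8 * 40, replace = TRUE), ncol = 8,
              dimnames = list(NULL, paste0("t", 1:8)))
  D <- distance_matrix(H)
  pt <- paco_test(D, D, n_perm = 199, seed = 1)
  expect_lt(pt$m2, 1e-10)
  expect_equal(pt$p, 1 / 200)
})

test_that("the sampled null matches full enumeration at five taxa", {
  set.seed(6)
  Dh <- as.matrix(dist(matrix(rnorm(10), 5)))
  Dp <- as.matrix(dist(matrix(rnorm(10), 5)))
  rownames(Dh) <- colnames(Dh) <- rownames(Dp) <- colnames(Dp) <- paste0("x", 1:5)
  X <- pcoa_embed(Dh); Y <- pcoa_embed(Dp)
  perms <- neowsweep:::all_permutations(5)
  m2_all <- apply(perms, 1, function(pp)
    neowsweep:::procrustes_m2(X, Y[pp, , drop = FALSE]))
  m2_obs <- neowsweep:::procrustes_m2(X, Y)
  p_enum <- mean(m2_all <= m2_obs + 1e-12)
  pt <- paco_test(Dh, Dp, n_perm = 2000, seed = 3)
  # every sampled statistic is one of the 120 enumerable values
  expect_equal(pt$m2, m2_obs, tolerance = 1e-12)
  expect_lt(abs(pt$p - p_enum), 0.06)
})

test_that("pairing validation and label-consistent relabelling", {
  D <- as.matrix(dist(matrix(rnorm(12), 6)))
  rownames(D) <- colnames(D) <- paste0("h", 1:6)
  Dp <- D; rownames(Dp) <- colnames(Dp) <- paste0("p", 1:6)
  pairing <- data.frame(host = paste0("h", 1:6), parasite = paste0("p", 1:6))
  pt <- paco_test(D, Dp, pairing, n_perm = 99, seed = 5)
  expect_lt(pt$m2, 1e-10)
  bad <- pairing; bad$parasite[2] <- "p1"
  expect_error(paco_test(D, Dp, bad), "bijection")
  # consistent relabelling leaves the statistic unchanged
  perm <- sample(6)
  D2 <- D[perm, perm]; Dp2 <- Dp[perm, perm]
  pairing2 <- data.frame(host = rownames(D2), parasite = rownames(Dp2))
  pt2 <- paco_test(D2, Dp2, pairing2, n_perm = 99, seed = 5)
  expect_equal(pt2$m2, pt$m2, tolerance = 1e-10)
})

test_that("tidiers expose the congruence result", {
  D <- as.matrix(dist(matrix(rnorm(12), 6)))
  rownames(D) <- colnames(D) <- paste0("h", 1:6)
  pt <- paco_test(D, D, n_perm = 49, seed = 1)
  td <- broom::tidy(pt)
  expect_equal(td$p.value, pt$p)
  expect_equal(td$n.perm, 49)
})
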