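test_that("LPA matrix reflects presence and supports exclusion", {
  ls <- tiny_locus_set()
  lpa <- build_lpa(ls)
  expect_equal(dim(lpa), c(3L, 2L))
  expect_equal(unname(lpa["sp1_b", ]), c(1L, 0L))
  expect_equal(rowSums(lpa),
               c(sp1_a = 2, sp1_b = 1, sp2_a = 2))
  expect_equal(dim(build_lpa(ls, exclude = "sp1_b")), c(2L, 2L))
  expect_equal(dim(build_lpa(locus_set())), c(0L, 0L))
})

test_that("shared-locus counts equal the brute-force double loop", {
  set.seed(4)
  for (rep in 1:10) {
    lpa <- matrix(rbinom(10 * 50, 1, 0.5), 10, 50,
                  dimnames = list(paste0("s", 1:10), paste0("L", 1:50)))
    sm <- shared_locus_summary(lpa)
    want <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10)
      want[i, j] <- sum(lpa[i, ] & lpa[j, ])
    expect_equal(unname(sm$counts), want)
    expect_true(all(sm$proportions >= 0 & sm$proportions <= 1))
    off <- sm$counts[upper.tri(sm$counts)]
    lim <- outer(diag(sm$counts), diag(sm$counts), pmin)[upper.tri(sm$counts)]
    expect_true(all(off <= lim))
  }
  two <- rbind(a = c(1, 1, 1, 1, 1, 0), b = c(1, 1, 1, 1, 1, 0))
  expect_equal(shared_locus_summary(two)$counts["a", "b"], 5)
})

test_that("Jaccard distances follow the set formula", {
  lpa <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1), c = c(1, 1, 1, 0),
               d = c(0, 0, 0, 1))
  d <- jaccard_distances(lpa)
  expect_equal(d["a", "b"], 0.5)      # {1,2,3} vs {2,3,4}
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_equal(diag(d), setNames(rep(0, 4), rownames(lpa)))
  expect_error(jaccard_distances(rbind(a = c(1, 0), b = c(0, 0))), "all-zero")
})

test_that("NMDS embeds easy geometries and reports the best restart", {
  # 3 collinear points embed perfectly in K = 1
  d3 <- as.matrix(dist(c(0, 1, 2)))
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  o1 <- nmds(d3, K = 1, n_restarts = 10, seed = 2)
  expect_lt(o1$stress, 1e-5)

  # 6 points on a circle: no monotone 1-D embedding, clean in K = 2
  ang <- 2 * pi * (0:5) / 6
  dc <- as.matrix(dist(cbind(cos(ang), sin(ang))))
  dimnames(dc) <- list(letters[1:6], letters[1:6])
  expect_gt(nmds(dc, K = 1, n_restarts = 10, seed = 3)$stress, 0.01)
  expect_lt(nmds(dc, K = 2, n_restarts = 20, seed = 3)$stress, 1e-4)

  d4 <- matrix(1, 4, 4) - diag(4)
  dimnames(d4) <- list(letters[1:4], letters[1:4])
  o <- nmds(d4, K = 2, n_restarts = 15, seed = 4)
  expect_equal(o$stress, min(o$stress_all))
  expect_identical(nmds(d4, K = 2, n_restarts = 5, seed = 9)$coordinates,
                   nmds(d4, K = 2, n_restarts = 5, seed = 9)$coordinates)
  expect_error(nmds(d4, K = 4), "smaller")
})

test_that("shared-locus models reproduce hand OLS and are order-invariant", {
  # y = [0,1,1,2] on x = [0,1,2,3]: slope 0.6, r2 = 0.9
  x <- c(0, 1, 2, 3); y <- c(0, 1, 1, 2)
  f <- lm(y ~ x)
  expect_equal(unname(coef(f)[2]), 0.6)
  expect_equal(summary(f)$r.squared, 0.9)

  set.seed(8)
  n <- 6
  lpa <- matrix(rbinom(n * 80, 1, 0.7), n, 80,
                dimnames = list(paste0("s", 1:n), NULL))
  sm <- shared_locus_summary(lpa)
  reads <- setNames(exp(rnorm(n, 15, 0.5)), rownames(lpa))
  pd <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(pd) <- list(rownames(lpa), rownames(lpa))
  fit <- fit_shared_locus_models(sm, reads, pd)
  expect_gte(fit$fitB$r2, fit$fitA$r2)
  expect_true(fit$fitA$r2 >= 0 && fit$fitB$r2 <= 1)

  # permuting sample order leaves the fits unchanged
  perm <- sample(n)
  sm2 <- shared_locus_summary(lpa[perm, ])
  fit2 <- fit_shared_locus_models(sm2, reads, pd)
  expect_equal(sort(unname(fit2$fitB$coefficients)),
               sort(unname(fit$fitB$coefficients)), tolerance = 1e-9)

  expect_error(fit_shared_locus_models(sm, setNames(rep(2, n), names(reads)),
                                       pd), "singular|constant")
})

test_that("exactly linear responses give r2 = 1", {
  sm <- structure(list(counts = matrix(0, 4, 4,
                         dimnames = list(letters[1:4], letters[1:4])),
                       proportions = NULL, n_loci = 10),
                  class = "shared_locus_summary")
  reads <- setNames(10^(1:4), letters[1:4])
  # shared_ij = log10 sqrt(Ri Rj) exactly
  for (i in 1:4) for (j in 1:4)
    sm$counts[i, j] <- log10(sqrt(reads[i] * reads[j]))
  pd <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  pd[] <- as.matrix(dist(1:4))
  fit <- suppressWarnings(fit_shared_locus_models(sm, reads, pd))
  expect_equal(fit$fitA$r2, 1, tolerance = 1e-12)
})

test_that("dropout simulations show the phylogenetic locus-sharing signal", {
  m <- transisthmian_model()
  cfg <- simulation_config(model = m, n_individuals = 2, n_loci = 250,
                           locus_length = 50, rate_alpha = 1,
                           dropout = TRUE,
                           depth = depth_model(0.95), seed = 23)
  sim <- simulate_dataset(cfg)
  ls <- sim$locus_set
  lpa <- build_lpa(ls)
  sm <- shared_locus_summary(lpa)
  reads <- setNames(ls$samples$reads_passing_filter, ls$samples$sample_id)
  phy <- isthmusclock:::species_time_tree(m)
  spd <- patristic_distances(phy)
  pd <- isthmusclock:::sample_distance_matrix(spd, ls$samples)
  fit <- fit_shared_locus_models(sm, reads, pd[rownames(lpa), rownames(lpa)])
  # distance adds real signal with a negative slope
  expect_gt(fit$fitB$r2, fit$fitA$r2)
  expect_lt(fit$fitB$coefficients[["phylo_dist"]], 0)
  expect_lt(fit$anova$p, 0.01)

  # NMDS of Jaccard distances clusters sister pairs
  ord <- nmds(jaccard_distances(lpa), K = 2, n_restarts = 10, seed = 5)
  co <- ord$coordinates
  sp <- setNames(ls$samples$species_id, ls$samples$sample_id)
  pair_of <- c(wonkimi = "WM", malleator = "WM", colombiensis = "EC",
               estuariensis = "EC", panamensis = "PF", formosus = "PF")
  pr <- pair_of[sp[rownames(co)]]
  dmat <- as.matrix(dist(co))
  within <- dmat[outer(pr, pr, "==") & upper.tri(dmat)]
  between <- dmat[outer(pr, pr, "!=") & upper.tri(dmat)]
  expect_lt(mean(within), mean(between))
})
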