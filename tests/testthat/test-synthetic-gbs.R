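test_that("single-population coalescence times match the analytic mean", {
  set.seed(101)
  sk <- one_pop(0.02)
  ages <- replicate(4000, { g <- simulate_genealogy(sk, c(sp = 2L)); g$age[g$root] })
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 0.01), 3 * se)
})

test_that("no cross-population coalescence below tau and no events at M = 0", {
  set.seed(3)
  m <- pair_model(tau = 0.01,
                  bands = data.frame(source = "A", target = "B", rate = 0))
  for (i in 1:50) {
    g <- simulate_genealogy(m, c(A = 2L, B = 2L))
    expect_equal(nrow(g$migrations), 0L)
    # cross-species coalescences are older than tau
    for (u in (g$n_tips + 1L):(2L * g$n_tips - 1L)) {
      tips_below <- intersect(unlist(descendants_of(g, u)), seq_len(g$n_tips))
      if (length(unique(g$tip_pop[tips_below])) > 1)
        expect_gte(g$age[u], 0.01)
    }
  }
})

test_that("JC69 overlay reproduces coalescent pairwise diversity", {
  set.seed(11)
  sk <- one_pop(0.02)
  pd <- replicate(1500, {
    g <- simulate_genealogy(sk, c(sp = 2L))
    h <- isthmusclock:::sim_haplotypes_int(g, 200, 1)
    mean(h[1, ] != h[2, ])
  })
  se <- sd(pd) / sqrt(length(pd))
  # JC saturation shaves a whisker off theta; analytic target:
  target <- 1 - integrate(function(t) 2 / 0.02 * exp(-2 * t / 0.02) *
    (0.25 + 0.75 * exp(-8 * t / 3)), 0, Inf)$value
  expect_lt(abs(mean(pd) - target), 3 * se)
})

test_that("cross-species divergence approximates 2*tau + theta_anc", {
  set.seed(12)
  m <- pair_model(theta = 0.02, tau = 0.01)
  pd <- replicate(1500, {
    g <- simulate_genealogy(m, c(A = 1L, B = 1L))
    h <- isthmusclock:::sim_haplotypes_int(g, 200, 1)
    mean(h[1, ] != h[2, ])
  })
  se <- sd(pd) / sqrt(length(pd))
  expect_lt(abs(mean(pd) - 0.0388), 3 * se + 0.001)  # JC-adjusted 0.04
})

test_that("zero rate leaves all tips identical to the root", {
  set.seed(5)
  g <- simulate_genealogy(one_pop(0.02), c(sp = 4L))
  seqs <- overlay_mutations(g, 50, r_l = 0)
  expect_length(unique(seqs), 1L)
})

test_that("restriction dropout matches the Poisson zero-count probability", {
  set.seed(21)
  # isolate a fixed root-to-tip path of 0.05 with a two-tip star
  m <- demographic_model("(A,B)root;", theta = 1e-9, tau = c(root = 0.05))
  ok <- replicate(4000, {
    g <- simulate_genealogy(m, c(A = 1L, B = 1L))
    apply_restriction_dropout(g, 6, 1)[[1]]
  })
  p <- exp(-6 * 0.05)
  se <- sqrt(p * (1 - p) / length(ok))
  expect_lt(abs(mean(ok) - p), 3 * se + 0.002)
})

test_that("deeper species pairs share fewer loci under identical theta", {
  set.seed(31)
  share <- vapply(c(0.005, 0.02, 0.06), function(tau) {
    m <- pair_model(theta = 0.01, tau = tau)
    mean(replicate(400, {
      g <- simulate_genealogy(m, c(A = 1L, B = 1L))
      all(apply_restriction_dropout(g, 6, 1))
    }))
  }, numeric(1))
  expect_true(all(diff(share) < 0))
})

test_that("depth missingness respects capture probabilities and ranks", {
  set.seed(41)
  pres <- matrix(TRUE, 20, 400,
                 dimnames = list(paste0("s", 1:20), NULL))
  p <- seq(0.05, 1, length.out = 20)
  names(p) <- rownames(pres)
  dm <- apply_depth_missingness(pres, depth_model(p))
  kept <- rowSums(dm$presence)
  expect_gt(cor(kept, p, method = "spearman"), 0.9)
  expect_equal(rank(dm$reads_passing_filter), rank(p))

  dm1 <- apply_depth_missingness(pres, depth_model(setNames(rep(1, 20), names(p))))
  expect_true(all(dm1$presence))
  p0 <- p; p0["s3"] <- 0
  dm0 <- apply_depth_missingness(pres, depth_model(p0))
  expect_equal(sum(dm0$presence["s3", ]), 0L)
})

test_that("simulate_dataset is deterministic and honors its switches", {
  m <- pair_model()
  cfg <- simulation_config(model = m, n_individuals = 2, n_loci = 25,
                           locus_length = 40, seed = 7)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))

  cfg2 <- simulation_config(model = m, n_individuals = 2, n_loci = 25,
                            locus_length = 40, dropout = FALSE,
                            depth = depth_model(1), seed = 7)
  sim <- simulate_dataset(cfg2)
  expect_equal(n_loci(sim$locus_set), 25L)
  expect_true(all(vapply(sim$locus_set$loci,
                         function(l) length(l$seqs) == 4L, logical(1))))
  expect_true(all(sim$truth$dropout$cause == "none"))

  cfg3 <- simulation_config(model = m, n_individuals = 2, n_loci = 25,
                            rate_alpha = "constant", seed = 7)
  expect_true(all(simulate_dataset(cfg3)$truth$rates$r_l == 1))
})

test_that("realized rate multipliers renormalize to mean exactly 1", {
  cfg <- simulation_config(model = pair_model(), n_individuals = 1,
                           n_loci = 60, rate_alpha = 0.7, seed = 2)
  rl <- simulate_dataset(cfg)$truth$rates$r_l
  expect_equal(mean(rl), 1, tolerance = 1e-12)
  expect_gt(sd(rl), 0)
})

test_that("heterozygous site frequency within a diploid tracks theta", {
  set.seed(55)
  m <- pair_model(theta = 0.02, tau = 0.05)
  cfg <- simulation_config(model = m, n_individuals = 1, n_loci = 250,
                           locus_length = 100, rate_alpha = "constant",
                           dropout = FALSE, depth = depth_model(1), seed = 55)
  sim <- simulate_dataset(cfg)
  het <- unlist(lapply(sim$locus_set$loci, function(l)
    vapply(l$seqs, function(s)
      mean(strsplit(s, "")[[1]] %in% names(isthmusclock:::IUPAC_HET)),
      numeric(1))))
  se <- sd(het) / sqrt(length(het))
  target <- 1 - integrate(function(t) 2 / 0.02 * exp(-2 * t / 0.02) *
    (0.25 + 0.75 * exp(-8 * t / 3)), 0, Inf)$value
  expect_lt(abs(mean(het) - target), 3 * se)
})

test_that("migration between sisters raises cross-species allele sharing", {
  set.seed(66)
  shared_variants <- function(M) {
    bands <- if (M > 0) data.frame(source = "A", target = "B", rate = M)
             else NULL
    m <- pair_model(theta = 0.02, tau = 0.01, bands = bands)
    cfg <- simulation_config(model = m, n_individuals = 2, n_loci = 150,
                             locus_length = 100, rate_alpha = "constant",
                             dropout = FALSE, depth = depth_model(1),
                             seed = 66 + round(M))
    sim <- simulate_dataset(cfg)
    snps <- extract_snps(sim$locus_set)
    sp <- setNames(sim$locus_set$samples$species_id,
                   sim$locus_set$samples$sample_id)
    both <- apply(snps$gt, 1, function(row) {
      seg <- function(s) {
        g <- row[names(row)[sp[names(row)] == s]]
        g <- g[!is.na(g)]
        length(unique(unlist(strsplit(g, "/")))) > 1
      }
      seg("A") && seg("B")
    })
    mean(both)
  }
  expect_gt(shared_variants(100), shared_variants(0))
})
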