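test_that("genealogy density matches hand-evaluated closed forms", {
  # n = 2: (2/theta) exp(-2t/theta)
  expect_equal(genealogy_log_density(gen_pair(0.005), one_pop(0.01)),
               log(200 * exp(-1)), tolerance = 1e-12)
  # n = 3, coalescences at 0.001 and 0.003, theta = 0.02:
  # (100)^2 exp(-(6*0.001 + 2*0.002)/0.02)
  expect_equal(genealogy_log_density(gen_triple(0.001, 0.003), one_pop(0.02)),
               log(1e4 * exp(-0.5)), tolerance = 1e-12)
})

test_that("inconsistent genealogies raise an error rather than -Inf", {
  m <- pair_model(tau = 0.01)
  ma <- isthmusclock:::model_arrays(m)
  g <- gen_pair(0.005)           # coalescence below tau between A and B
  g$tip_pop <- c(1L, 2L); g$pop <- c(1L, 2L, 3L)
  expect_error(genealogy_log_density(g, ma), "inconsistent")
})

test_that("coalescent density integrates to one (n = 2) and 1/3 (fixed n = 3 history)", {
  f2 <- Vectorize(function(t)
    exp(genealogy_log_density(gen_pair(t), one_pop(0.02))))
  expect_equal(integrate(f2, 0, Inf)$value, 1, tolerance = 1e-6)

  # one labeled 3-lineage history; its density integrates to 1/3 over
  # 0 < t1 < t2 (three equiprobable pair choices sum to 1)
  f3 <- function(t1, t2)
    exp(genealogy_log_density(gen_triple(t1, t2), one_pop(0.02)))
  inner <- Vectorize(function(t1)
    integrate(Vectorize(function(t2) f3(t1, t2)), t1, Inf)$value)
  expect_equal(integrate(inner, 0, Inf)$value, 1 / 3, tolerance = 1e-5)
})

test_that("pair likelihood matches the JC69 closed form", {
  # total path 0.3, same base: (1/4)(1/4 + 3/4 e^{-0.4})
  g <- gen_pair(0.15)
  expect_equal(exp(locus_log_likelihood(g, "A")),
               0.25 * (0.25 + 0.75 * exp(-0.4)), tolerance = 1e-12)
  # zero distance, same base: 1/4
  expect_equal(exp(locus_log_likelihood(gen_pair(0), "A")), 0.25,
               tolerance = 1e-12)
  # heterozygous site sums both phasings (= 2x either one, by symmetry)
  ps <- 0.25 + 0.75 * exp(-0.4); pd <- (1 - ps) / 3
  expect_equal(exp(locus_log_likelihood(g, "R")), 2 * 0.25 * pd,
               tolerance = 1e-12)
  # r_l scales branch lengths
  expect_equal(exp(locus_log_likelihood(gen_pair(0.3), "A", r_l = 0.5)),
               0.25 * (0.25 + 0.75 * exp(-0.4)), tolerance = 1e-12)
})

test_that("pruning equals brute-force state enumeration (<= 5 tips)", {
  set.seed(71)
  m <- pair_model(theta = 0.02, tau = 0.006)
  for (rep in 1:8) {
    g <- simulate_genealogy(m, c(A = 2L, B = 2L))
    # random homozygous/missing tip data, checked site by site
    for (site in 1:4) {
      tips <- sample(c(1:4, NA), g$n_tips, replace = TRUE)
      want <- brute_force_site_lik(g, tips)
      seqs <- vapply(seq_len(g$n_tips / 2), function(i) {
        a <- tips[2 * i - 1]; b <- tips[2 * i]
        if (is.na(a) || is.na(b)) return("N")    # pair coded jointly below
        collapse_haplotypes(c("A", "C", "G", "T")[a], c("A", "C", "G", "T")[b])
      }, character(1))
      # restrict to fully homozygous-or-missing diploids so the genotype
      # encoding is exact (phased cases covered in the phasing test)
      hom <- vapply(seq_len(g$n_tips / 2), function(i)
        is.na(tips[2 * i - 1]) == is.na(tips[2 * i]) &&
          (is.na(tips[2 * i - 1]) || tips[2 * i - 1] == tips[2 * i]),
        logical(1))
      if (!all(hom)) next
      got <- exp(locus_log_likelihood(g, seqs))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("per-site phasing summation equals whole-locus phasing enumeration", {
  set.seed(73)
  m <- pair_model(theta = 0.03, tau = 0.004)
  for (rep in 1:5) {
    g <- simulate_genealogy(m, c(A = 2L, B = 2L))
    haps <- overlay_mutations(g, 6, 1.3)
    dips <- c(collapse_haplotypes(haps[1], haps[2]),
              collapse_haplotypes(haps[3], haps[4]))
    for (r_l in c(0.5, 1, 2)) {
      got <- locus_log_likelihood(g, dips, r_l)
      # enumerate all whole-locus phasings explicitly
      chars <- strsplit(dips, "")
      het_pos <- lapply(chars, function(x)
        which(x %in% names(isthmusclock:::IUPAC_HET)))
      h <- sum(lengths(het_pos))
      total <- 0
      for (mask in 0:(2^h - 1)) {
        bits <- as.integer(intToBits(mask))[seq_len(max(h, 1))]
        tipseq <- character(4)
        bit <- 1
        for (i in 1:2) {
          a <- chars[[i]]; b <- chars[[i]]
          for (p in het_pos[[i]]) {
            al <- isthmusclock:::iupac_alleles(a[p])
            if (h > 0 && bits[bit] == 1) al <- rev(al)
            a[p] <- al[1]; b[p] <- al[2]
            bit <- bit + 1
          }
          tipseq[2 * i - 1] <- paste(a, collapse = "")
          tipseq[2 * i] <- paste(b, collapse = "")
        }
        site_l <- 1
        for (s in 1:6) {
          st <- match(substring(tipseq, s, s), c("A", "C", "G", "T"))
          site_l <- site_l * brute_force_site_lik(g, st, r_l)
        }
        total <- total + site_l
      }
      expect_equal(exp(got), total, tolerance = 1e-9)
    }
  }
})

test_that("initialize_state is valid, ordered and deterministic", {
  cfg <- simulation_config(model = pair_model(), n_individuals = 2,
                           n_loci = 10, locus_length = 30, seed = 2)
  ls <- simulate_dataset(cfg)$locus_set
  s1 <- initialize_state(ls, "(A,B)root;", priors = prior_spec(), seed = 4)
  s2 <- initialize_state(ls, "(A,B)root;", priors = prior_spec(), seed = 4)
  expect_identical(s1$skeleton$theta, s2$skeleton$theta)
  expect_identical(s1$gens[[1]]$age, s2$gens[[1]]$age)
  # every genealogy is consistent with the drawn model
  for (g in s1$gens) {
    res <- isthmusclock:::gen_density_cpp(isthmusclock:::gen_to_cpp(g),
                                          s1$skeleton)
    expect_true(res$valid)
  }
  # tau ordering holds over many random draws on a deeper tree
  tr <- transisthmian_tree()
  sk <- isthmusclock:::tree_skeleton(tr)
  for (i in 1:200) {
    st <- initialize_state(locus_set(), tr, priors = prior_spec(), seed = i)
    tau <- st$skeleton$tau
    par <- st$skeleton$parent
    for (p in seq_along(par))
      if (par[p] >= 0) expect_lt(tau[p], tau[par[p] + 1])
  }
})

test_that("the sampler is deterministic under its seed", {
  cfg <- simulation_config(model = pair_model(), n_individuals = 2,
                           n_loci = 25, locus_length = 40, seed = 5)
  ls <- simulate_dataset(cfg)$locus_set
  st <- mcmc_settings(burn_in = 50, n_iterations = 200, sample_every = 5,
                      finetune_window = 40, seed = 9)
  t1 <- suppressWarnings(run_mcmc(ls, "(A,B)root;", settings = st))
  t2 <- suppressWarnings(run_mcmc(ls, "(A,B)root;", settings = st))
  expect_identical(t1$trace, t2$trace)
  expect_equal(nrow(t1$trace), 40L)   # n_iterations / sample_every
})

test_that("effective sample size behaves on known processes", {
  set.seed(31)
  x <- rnorm(4000)
  expect_gt(effective_sample_size(x), 0.8 * 4000)
  expect_lt(effective_sample_size(x), 1.25 * 4000)
  expect_equal(effective_sample_size(rep(3.14, 500)), 1)
  y <- as.numeric(arima.sim(list(ar = 0.5), 20000))
  expect_lt(abs(effective_sample_size(y) - 20000 / 3) / (20000 / 3), 0.25)
  expect_error(effective_sample_size(rnorm(50)), "at least 100")
})

test_that("traces round-trip through the Tracer-compatible format", {
  cfg <- simulation_config(model = pair_model(), n_individuals = 1,
                           n_loci = 5, locus_length = 20, seed = 1)
  ls <- simulate_dataset(cfg)$locus_set
  st <- mcmc_settings(burn_in = 20, n_iterations = 100, sample_every = 10,
                      finetune_window = 0, seed = 2)
  tr <- suppressWarnings(run_mcmc(ls, "(A,B)root;", settings = st))
  p <- withr::local_tempfile(fileext = ".trace")
  write_trace(tr, p)
  hdr <- strsplit(readLines(p, n = 1), "\t")[[1]]
  expect_equal(hdr[1], "Sample")
  back <- read_trace(p)
  expect_equal(unname(back$trace), unname(tr$trace), tolerance = 1e-6)
})
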