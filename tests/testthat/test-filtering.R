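test_that("dataset names parse into cohort/m/s filter specs", {
  s <- parse_dataset_name("Am4s2")
  expect_equal(s$cohort, "A"); expect_equal(s$m, 4L); expect_equal(s$s, 2L)
  s2 <- parse_dataset_name("23m6s2")
  expect_equal(s2$cohort, "23"); expect_equal(s2$m, 6L); expect_equal(s2$s, 2L)
  s3 <- parse_dataset_name("Am3s3")
  expect_equal(s3$m, 3L); expect_equal(s3$s, 3L)
  expect_error(parse_dataset_name("m4s2"), "malformed")
  expect_error(parse_dataset_name("Am4"), "malformed")
})

test_that("paralog heterozygosity caps apply per sequence then per site", {
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        species_id = c("x", "x", "y"),
                        stringsAsFactors = FALSE)
  het9 <- paste(c(rep("R", 9), rep("A", 3)), collapse = "")
  het8 <- paste(c(rep("R", 8), rep("A", 4)), collapse = "")
  hom <- strrep("A", 12)
  ls <- locus_set(list(
    list(locus_id = "L1", seqs = c(a = het9, b = hom, c = hom)),
    list(locus_id = "L2", seqs = c(a = het8, b = hom, c = hom)),
    list(locus_id = "L3", seqs = c(a = paste0("R", strrep("A", 11)),
                                   b = paste0("R", strrep("A", 11)),
                                   c = paste0("R", strrep("A", 11))))),
    samples)
  out <- apply_paralog_filters(ls)
  # >8 het sites: that sequence removed, locus retained with the rest
  expect_false("a" %in% names(out$loci[[match("L1", locus_ids(out))]]$seqs))
  # exactly 8 het sites: retained
  expect_true("a" %in% names(out$loci[[match("L2", locus_ids(out))]]$seqs))
  # site heterozygous in 3 samples: whole locus discarded
  expect_false("L3" %in% locus_ids(out))
})

test_that("m/s filter counts individuals and species", {
  samples <- data.frame(sample_id = c("sp1_a", "sp1_b", "sp2_a"),
                        species_id = c("sp1", "sp1", "sp2"),
                        stringsAsFactors = FALSE)
  ls <- locus_set(list(list(locus_id = "L1",
                            seqs = c(sp1_a = "AC", sp1_b = "AC", sp2_a = "AC"))),
                  samples)
  expect_equal(n_loci(apply_ms_filter(ls, filter_spec(m = 3, s = 2))), 1L)
  expect_equal(n_loci(apply_ms_filter(ls, filter_spec(m = 4, s = 2))), 0L)
  expect_equal(locus_ids(apply_ms_filter(ls, filter_spec(m = 1, s = 1))),
               locus_ids(ls))
  # an all-N sequence counts as absent
  ls2 <- locus_set(list(list(locus_id = "L1",
                             seqs = c(sp1_a = "AC", sp2_a = "NN"))), samples)
  expect_equal(n_loci(apply_ms_filter(ls2, filter_spec(m = 1, s = 2))), 0L)
})

test_that("m/s filter agrees with a brute-force recount on random masks", {
  set.seed(9)
  samples <- data.frame(sample_id = paste0("s", 1:8),
                        species_id = rep(c("w", "x", "y", "z"), each = 2),
                        stringsAsFactors = FALSE)
  for (rep in 1:20) {
    mask <- matrix(runif(8 * 30) < 0.6, 8, 30)
    loci <- lapply(1:30, function(l) {
      present <- samples$sample_id[mask[, l]]
      if (!length(present)) present <- "s1"
      list(locus_id = sprintf("L%02d", l),
           seqs = setNames(rep("ACGT", length(present)), present))
    })
    ls <- locus_set(loci, samples)
    m <- sample(1:5, 1); s <- sample(1:3, 1)
    got <- n_loci(apply_ms_filter(ls, filter_spec(m = m, s = s)))
    want <- sum(vapply(loci, function(l) {
      sp <- samples$species_id[match(names(l$seqs), samples$sample_id)]
      length(l$seqs) >= m && length(unique(sp)) >= s
    }, logical(1)))
    expect_equal(got, want)
  }
})

test_that("m/s filters compose and are monotone", {
  set.seed(10)
  cfg <- simulation_config(model = pair_model(), n_individuals = 3,
                           n_loci = 60, locus_length = 30, seed = 3)
  ls <- simulate_dataset(cfg)$locus_set
  a <- apply_ms_filter(apply_ms_filter(ls, filter_spec(m = 3, s = 1)),
                       filter_spec(m = 4, s = 2))
  b <- apply_ms_filter(ls, filter_spec(m = 4, s = 2))
  expect_equal(locus_ids(a), locus_ids(b))
  counts <- outer(1:5, 1:2, Vectorize(function(m, s)
    n_loci(apply_ms_filter(ls, filter_spec(m = m, s = s)))))
  expect_true(all(diff(counts[, 1]) <= 0))
  expect_true(all(counts[, 2] <= counts[, 1]))
})

test_that("neutral/coding partition is disjoint and exhaustive", {
  ls <- tiny_locus_set()
  p0 <- partition_neutral(ls, character())
  expect_equal(locus_ids(p0$neutral), locus_ids(ls))
  expect_equal(n_loci(p0$coding), 0L)
  p1 <- partition_neutral(ls, locus_ids(ls))
  expect_equal(n_loci(p1$neutral), 0L)
  expect_warning(p2 <- partition_neutral(ls, c("L1", "nope")), "unknown")
  expect_equal(n_loci(p2$neutral) + n_loci(p2$coding), n_loci(ls))
})

test_that("SNP extraction expands ambiguities and matches a census oracle", {
  ls <- tiny_locus_set()
  snps <- extract_snps(ls)
  # L1 site 2 (0-based): A/A, A/A, A/G het -> one biallelic row
  expect_equal(nrow(snps$sites), 2L)
  r1 <- snps$sites[snps$sites$locus_id == "L1", ]
  expect_equal(r1$site, 2L)
  expect_equal(r1$alleles, "A/G")
  expect_true(r1$biallelic)
  expect_equal(unname(snps$gt[1, "sp2_a"]), "A/G")

  # invariant locus contributes no rows
  inv <- locus_set(list(list(locus_id = "L1", seqs = c(a = "AAAA", b = "AAAA"))))
  expect_equal(nrow(extract_snps(inv)$sites), 0L)

  set.seed(13)
  for (rep in 1:10) {
    ls2 <- random_locus_set(4, 3, 10)
    got <- nrow(extract_snps(ls2)$sites)
    want <- sum(vapply(ls2$loci, function(l) {
      m <- do.call(rbind, strsplit(l$seqs, ""))
      sum(apply(m, 2, function(col) {
        al <- unlist(lapply(col, isthmusclock:::iupac_alleles))
        length(unique(al)) >= 2
      }))
    }, numeric(1)))
    expect_equal(got, want)
  }
})

test_that("Ts/Tv ratio follows the transition definition", {
  mk <- function(allele_sets) {
    sites <- data.frame(locus_id = "L", site = seq_along(allele_sets),
                        alleles = allele_sets,
                        n_alleles = 2L, biallelic = TRUE,
                        stringsAsFactors = FALSE)
    structure(list(sites = sites,
                   gt = matrix(NA_character_, length(allele_sets), 0),
                   samples = character()), class = "snp_table")
  }
  expect_equal(ts_tv_ratio(mk(c("A/G", "C/T", "A/C", "G/T"))), 1.0)
  expect_equal(ts_tv_ratio(mk(c("A/G", "A/G", "A/T"))), 2.0)
  expect_warning(r <- ts_tv_ratio(mk(c("A/G"))), "transversions")
  expect_equal(r, Inf)
})

test_that("JC69-simulated SNPs give Ts/Tv near 0.5 and a flat spectrum", {
  cfg <- simulation_config(model = pair_model(theta = 0.01, tau = 0.02),
                           n_individuals = 2, n_loci = 300, locus_length = 80,
                           rate_alpha = "constant", dropout = FALSE,
                           depth = depth_model(1), seed = 99)
  snps <- extract_snps(simulate_dataset(cfg)$locus_set)
  n <- sum(snps$sites$biallelic)
  r <- ts_tv_ratio(snps)
  # transitions are binomial(n, 1/3) under JC symmetry
  p_hat <- r / (1 + r)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(p_hat - 1 / 3), 3 * se)
  spec <- substitution_spectrum(snps)
  expect_equal(sum(spec$count), n)
  expect_equal(sum(spec$proportion), 1)
  se6 <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(spec$proportion - 1 / 6) < 4 * se6))
})

test_that("substitution spectrum counts the six unordered pairs", {
  sites <- data.frame(locus_id = "L", site = 1:3,
                      alleles = c("A/C", "A/C", "C/T"),
                      n_alleles = 2L, biallelic = TRUE, stringsAsFactors = FALSE)
  snps <- structure(list(sites = sites, gt = matrix(NA_character_, 3, 0),
                         samples = character()), class = "snp_table")
  spec <- substitution_spectrum(snps)
  expect_equal(spec$count[spec$pair == "A/C"], 2)
  expect_equal(spec$count[spec$pair == "C/T"], 1)
  expect_equal(sum(spec$count), 3)
  empty <- structure(list(sites = sites[0, ], gt = matrix(NA_character_, 0, 0),
                          samples = character()), class = "snp_table")
  expect_true(all(substitution_spectrum(empty)$count == 0))
})

test_that("random subsets are deterministic, unique within, free across", {
  ls <- random_locus_set(30, 3, 8)
  s1 <- random_subsets(ls, 3, 10, seed = 5)
  s2 <- random_subsets(ls, 3, 10, seed = 5)
  expect_identical(lapply(s1, locus_ids), lapply(s2, locus_ids))
  expect_true(all(vapply(s1, function(x) !anyDuplicated(locus_ids(x)),
                         logical(1))))
  full <- random_subsets(ls, 2, 30, seed = 1)
  for (f in full) expect_setequal(locus_ids(f), locus_ids(ls))
  expect_error(random_subsets(ls, 1, 31, seed = 1), "exceeds")
})

test_that("strict species filters retain conserved (low-rate) loci", {
  tree <- "((A,B)AB,C)root;"
  m <- demographic_model(tree,
                         theta = setNames(rep(0.02, 5),
                                          c("A", "B", "C", "AB", "root")),
                         tau = c(AB = 0.006, root = 0.04))
  cfg <- simulation_config(model = m, n_individuals = 2, n_loci = 300,
                           locus_length = 60, rate_alpha = 1, dropout = TRUE,
                           depth = depth_model(1), seed = 17)
  sim <- simulate_dataset(cfg)
  rl <- setNames(sim$truth$rates$r_l, sim$truth$rates$locus_id)
  f1 <- apply_ms_filter(sim$locus_set, filter_spec(m = 2, s = 1))
  f3 <- apply_ms_filter(sim$locus_set, filter_spec(m = 2, s = 3))
  expect_lt(mean(rl[locus_ids(f3)]), mean(rl[locus_ids(f1)]))
})

test_that("snp tables export as minimal VCF", {
  snps <- extract_snps(tiny_locus_set())
  p <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(snps, p)
  lines <- readLines(p)
  expect_equal(sum(!startsWith(lines, "#")), nrow(snps$sites))
  body <- strsplit(lines[!startsWith(lines, "#")][1], "\t")[[1]]
  expect_equal(body[1], "L1")
  expect_equal(body[2], "3")   # 0-based site 2 -> POS 3
})
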