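# shared in-code fixtures and independent oracles

# small locus_set with two loci over three samples (one heterozygous site)
tiny_locus_set <- function() {
  samples <- data.frame(sample_id = c("sp1_a", "sp1_b", "sp2_a"),
                        species_id = c("sp1", "sp1", "sp2"),
                        reads_passing_filter = c(1e6, 2e6, 3e6),
                        stringsAsFactors = FALSE)
  loci <- list(
    list(locus_id = "L1",
         seqs = c(sp1_a = "ACGTAC", sp1_b = "ACGTAC", sp2_a = "ACRTAC")),
    list(locus_id = "L2",
         seqs = c(sp1_a = "TTTTTT", sp2_a = "TTTTGT")))
  locus_set(loci, samples)
}

# random locus_set for round-trip properties
random_locus_set <- function(n_loci = 5, n_samples = 4, len = 12) {
  alpha <- c("A", "C", "G", "T", "R", "Y", "N")
  smp <- paste0("s", seq_len(n_samples))
  loci <- lapply(seq_len(n_loci), function(i) {
    present <- smp[runif(n_samples) < 0.8]
    if (!length(present)) present <- smp[1]
    seqs <- vapply(present, function(s)
      paste(sample(alpha, len, replace = TRUE, prob = c(rep(4, 4), 1, 1, 1)),
            collapse = ""), character(1))
    list(locus_id = sprintf("L%03d", i), seqs = seqs)
  })
  locus_set(loci, data.frame(sample_id = smp,
                             species_id = rep(c("x", "y"), length.out = n_samples),
                             stringsAsFactors = FALSE))
}

# hand-built two-tip genealogy: one population, coalescence at `t`
gen_pair <- function(t, pop = 1L) {
  structure(list(
    n_tips = 2L, tip_label = c("d1.a", "d1.b"), tip_pop = c(pop, pop),
    parent = c(3L, 3L, NA), child = rbind(c(NA, NA), c(NA, NA), c(1L, 2L)),
    age = c(0, 0, t), pop = c(pop, pop, pop), root = 3L,
    migrations = data.frame(node = integer(), time = numeric(),
                            pop_below = integer(), pop_above = integer())),
    class = "genealogy")
}

# three tips, one population, coalescences at t1 < t2 ((1,2) first)
gen_triple <- function(t1, t2) {
  structure(list(
    n_tips = 3L, tip_label = c("a", "b", "c"), tip_pop = c(1L, 1L, 1L),
    parent = c(4L, 4L, 5L, 5L, NA),
    child = rbind(c(NA, NA), c(NA, NA), c(NA, NA), c(1L, 2L), c(4L, 3L)),
    age = c(0, 0, 0, t1, t2), pop = rep(1L, 5), root = 5L,
    migrations = data.frame(node = integer(), time = numeric(),
                            pop_below = integer(), pop_above = integer())),
    class = "genealogy")
}

# single-population model arrays with a given theta
one_pop <- function(theta, label = "sp") {
  list(npop = 1L, n_leaf = 1L, parent = -1L, tau = 0, theta = theta,
       band_src = integer(), band_tgt = integer(), band_rate = numeric(),
       labels = label)
}

# JC69 transition probability matrix for branch length d
jc_P <- function(d) {
  e <- exp(-4 * d / 3)
  m <- matrix(0.25 - 0.25 * e, 4, 4)
  diag(m) <- 0.25 + 0.75 * e
  m
}

# brute-force JC69 likelihood: sum over all internal node states,
# haploid tip states given as integer vector (1..4) per tip, NA = missing
brute_force_site_lik <- function(g, tip_states, r_l = 1) {
  nn <- 2L * g$n_tips - 1L
  internal <- setdiff(seq_len(nn), seq_len(g$n_tips))
  P <- lapply(seq_len(nn), function(v) {
    if (is.na(g$parent[v])) NULL
    else jc_P(r_l * (g$age[g$parent[v]] - g$age[v]))
  })
  states <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    s <- integer(nn)
    s[internal] <- states[r, ]
    pr <- 0.25                       # uniform root frequency
    ok <- TRUE
    for (v in seq_len(nn)) {
      if (is.na(g$parent[v])) next
      pv <- s[g$parent[v]]
      if (v <= g$n_tips) {
        if (is.na(tip_states[v])) next     # marginalized tip
        pr <- pr * P[[v]][pv, tip_states[v]]
      } else pr <- pr * P[[v]][pv, s[v]]
      if (pr == 0) { ok <- FALSE; break }
    }
    if (ok) tot <- tot + pr
  }
  tot
}

# brute-force patristic distances: BFS over the tree graph
graph_patristic <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]; w <- phy$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(NA_real_, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (src in seq_len(n)) {
    dist <- rep(NA_real_, nn); dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]
        if (is.na(dist[u])) { dist[u] <- dist[v] + adj[[v]][k, 2]; queue <- c(queue, u) }
      }
    }
    d[src, ] <- dist[seq_len(n)]
  }
  d
}

# tip indices below a genealogy node
descendants_of <- function(g, u) {
  if (u <= g$n_tips) return(u)
  c(descendants_of(g, g$child[u, 1]), descendants_of(g, g$child[u, 2]))
}

# collapse two haplotype strings into one unphased IUPAC sequence
collapse_haplotypes <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  paste(mapply(function(p, q) if (p == q) p else
    isthmusclock:::iupac_code(p, q), av, bv), collapse = "")
}

# quick 2-species demographic model
pair_model <- function(theta = 0.02, tau = 0.006, bands = NULL,
                       labels = c("A", "B")) {
  demographic_model(sprintf("(%s,%s)root;", labels[1], labels[2]),
                    theta = theta, tau = c(root = tau), bands = bands)
}
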