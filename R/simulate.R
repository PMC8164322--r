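#' Simulate a genealogy under the structured coalescent with migration
#'
#' Samples one locus genealogy backward in time under an
#' isolation-with-migration model: within population `b` holding `k`
#' lineages, coalescences occur at total rate \eqn{k(k-1)/\Theta_b}
#' (pairwise rate \eqn{2/\Theta_b}); each lineage resident in a migration
#' band's target population jumps (backward in time) to the source
#' population at rate `M` while both populations coexist; at each
#' divergence time the daughter populations' surviving lineages merge into
#' the ancestor. Uses R's RNG stream.
#'
#' @param model a [demographic_model()].
#' @param lineages named integer vector: haploid lineage count per species.
#' @param tip_labels optional labels for the haploid tips (defaults to
#'   `<species>.<i>`).
#' @return object of class `genealogy`: arrays `parent`, `child`, `age`
#'   (tau units), `pop` (population index at node birth), `tip_label`,
#'   `tip_pop`, and a `migrations` data frame (`node`, `time`, `pop_below`,
#'   `pop_above`; backward in time the lineage moves below->above).
#' @export
simulate_genealogy <- function(model, lineages, tip_labels = NULL) {
  ma <- if (inherits(model, "demographic_model")) model_arrays(model) else model
  parent_pop <- ifelse(ma$parent < 0, NA_integer_, ma$parent + 1L)
  tau <- ma$tau; theta <- ma$theta
  pop_end <- ifelse(is.na(parent_pop), Inf, tau[parent_pop])
  sp_idx <- match(names(lineages), ma$labels)
  if (anyNA(sp_idx)) stop("unknown species: ",
                          paste(names(lineages)[is.na(sp_idx)], collapse = ", "))
  tip_pop <- rep(sp_idx, lineages)
  N <- length(tip_pop)
  if (N < 2L) stop("need at least 2 lineages")
  if (is.null(tip_labels))
    tip_labels <- unlist(lapply(seq_along(lineages), function(k)
      paste0(names(lineages)[k], ".", seq_len(lineages[k]))))

  nnode <- 2L * N - 1L
  parent <- rep(NA_integer_, nnode)
  child <- matrix(NA_integer_, nnode, 2)
  age <- numeric(nnode)
  pop_birth <- integer(nnode)
  pop_birth[seq_len(N)] <- tip_pop
  mig_node <- integer(); mig_time <- numeric()
  mig_below <- integer(); mig_above <- integer()

  active <- seq_len(N)
  lpop <- tip_pop                      # current population per active lineage
  t <- 0
  nxt <- N                             # last created node id
  taus <- sort(unique(tau[tau > 0]))
  nb <- length(ma$band_rate)

  while (length(active) > 1L) {
    boundary <- if (length(taus)) taus[1] else Inf
    k <- tabulate(lpop, nbins = ma$npop)
    rc <- k * (k - 1) / theta
    rm <- numeric(nb)
    if (nb) for (j in seq_len(nb)) {
      s <- ma$band_src[j] + 1L; b <- ma$band_tgt[j] + 1L
      lo <- max(tau[s], tau[b]); hi <- min(pop_end[s], pop_end[b])
      if (t >= lo - 1e-15 && t < hi) rm[j] <- k[b] * ma$band_rate[j]
    }
    total <- sum(rc) + sum(rm)
    dt <- if (total > 0) rexp(1, total) else Inf
    if (t + dt >= boundary) {
      t <- boundary
      taus <- taus[-1]
      repeat {                          # funnel lineages into ancestors
        up <- !is.na(parent_pop[lpop]) & pop_end[lpop] <= t + 1e-15
        if (!any(up)) break
        lpop[up] <- parent_pop[lpop[up]]
      }
      next
    }
    t <- t + dt
    u <- runif(1) * total
    if (u < sum(rc)) {                  # coalescence
      p <- which(cumsum(rc) >= u)[1]
      in_p <- which(lpop == p)
      pair <- in_p[sample.int(length(in_p), 2L)]
      nxt <- nxt + 1L
      parent[active[pair]] <- nxt
      child[nxt, ] <- active[pair]
      age[nxt] <- t
      pop_birth[nxt] <- p
      active <- c(active[-pair], nxt)
      lpop <- c(lpop[-pair], p)
    } else {                            # backward migration target -> source
      u <- u - sum(rc)
      j <- which(cumsum(rm) >= u)[1]
      s <- ma$band_src[j] + 1L; b <- ma$band_tgt[j] + 1L
      in_b <- which(lpop == b)
      i <- in_b[sample.int(length(in_b), 1L)]
      mig_node <- c(mig_node, active[i]); mig_time <- c(mig_time, t)
      mig_below <- c(mig_below, b); mig_above <- c(mig_above, s)
      lpop[i] <- s
    }
  }
  structure(list(n_tips = N, tip_label = tip_labels, tip_pop = tip_pop,
                 parent = parent, child = child, age = age, pop = pop_birth,
                 root = active, labels = ma$labels,
                 migrations = data.frame(node = mig_node, time = mig_time,
                                         pop_below = mig_below,
                                         pop_above = mig_above)),
            class = "genealogy")
}

# nodes ordered root first, then decreasing age (parents precede children)
preorder_nodes <- function(g) {
  ord <- order(-g$age, seq_along(g$age))
  ord[ord == g$root][1]
  c(g$root, setdiff(ord, g$root))
}

# integer haplotype matrix (tips x sites), bases coded 1..4 = A,C,G,T
sim_haplotypes_int <- function(g, length, r_l) {
  nn <- 2L * g$n_tips - 1L
  seqs <- matrix(NA_integer_, nn, length)
  seqs[g$root, ] <- sample.int(4L, length, replace = TRUE)
  for (v in preorder_nodes(g)) {
    if (v == g$root) next
    d <- r_l * (g$age[g$parent[v]] - g$age[v])
    e <- exp(-4 * d / 3)
    s <- seqs[g$parent[v], ]
    ch <- runif(length) < 0.75 * (1 - e)
    if (any(ch))
      s[ch] <- 1L + (s[ch] - 1L + sample.int(3L, sum(ch), replace = TRUE)) %% 4L
    seqs[v, ] <- s
  }
  seqs[seq_len(g$n_tips), , drop = FALSE]
}

#' Overlay JC69 mutations on a genealogy
#'
#' The root sequence is uniform over A,C,G,T per site; along each branch of
#' tau-length \eqn{\ell} every site mutates independently under
#' Jukes-Cantor with expected `r_l * l` substitutions per site (exact
#' transition-probability sampling at branch ends).
#'
#' @param g a `genealogy`.
#' @param length locus length in bp.
#' @param r_l positive per-locus rate multiplier.
#' @return named character vector: one sequence per haploid tip.
#' @export
overlay_mutations <- function(g, length, r_l = 1) {
  stopifnot(r_l >= 0)
  m <- sim_haplotypes_int(g, length, r_l)
  seqs <- apply(m, 1L, function(row) paste(c("A", "C", "G", "T")[row],
                                           collapse = ""))
  stats::setNames(seqs, g$tip_label)
}

#' Restriction-site allelic dropout on a genealogy
#'
#' A recognition-site segment of `site_length` bp evolves on the same
#' genealogy (Poisson substitution counts per branch at rate
#' `site_length * r_l` per unit tau-length); an allele is lost iff at least
#' one substitution hit the segment anywhere on its root-to-tip path, so
#' mutations on internal branches knock out whole clades — the
#' phylogenetically structured missingness characteristic of GBS data.
#'
#' @param g a `genealogy`.
#' @param site_length recognition-site length in bp (EcoT22I: 6).
#' @param r_l per-locus rate multiplier (shared with the locus body, which
#'   couples conserved loci to conserved cut sites).
#' @return named logical vector per haploid tip: `TRUE` = allele present.
#' @export
apply_restriction_dropout <- function(g, site_length = 6, r_l = 1) {
  stopifnot(site_length >= 1)
  nn <- 2L * g$n_tips - 1L
  intact <- rep(TRUE, nn)
  for (v in preorder_nodes(g)) {
    if (v == g$root) next
    d <- site_length * r_l * (g$age[g$parent[v]] - g$age[v])
    hit <- rpois(1L, d) > 0L
    intact[v] <- intact[g$parent[v]] && !hit
  }
  stats::setNames(intact[seq_len(g$n_tips)], g$tip_label)
}

#' Per-sample sequencing-depth model
#'
#' Capture probability `p` per sample (probability that a locus surviving
#' restriction digestion is actually genotyped in that sample), plus a
#' log-normal model of total QC-passing reads whose ranks match the ranks
#' of `p` exactly.
#'
#' @param p named numeric vector of per-sample capture probabilities in
#'   `[0,1]`, or a single value recycled by the caller.
#' @param meanlog,sdlog log-normal read-count parameters; defaults emulate
#'   roughly 7.4 million reads per sample with a 45% coefficient of
#'   variation, typical of a multiplexed GBS lane.
#' @return object of class `depth_model`.
#' @export
depth_model <- function(p = 1, meanlog = log(7.35e6), sdlog = 0.43) {
  stopifnot(all(p >= 0 & p <= 1))
  structure(list(p = p, meanlog = meanlog, sdlog = sdlog),
            class = "depth_model")
}

#' Depth-driven missingness on a presence matrix
#'
#' Each surviving (sample, locus) cell is independently retained with the
#' sample's capture probability; simulated total read counts per sample are
#' log-normal with ranks identical to the capture-probability ranks.
#'
#' @param presence logical matrix samples x loci.
#' @param depth a [depth_model()]; `p` recycled/matched to rownames.
#' @return list: `presence` (updated matrix), `reads_passing_filter`
#'   (named numeric per sample).
#' @export
apply_depth_missingness <- function(presence, depth = depth_model()) {
  smp <- rownames(presence)
  p <- depth$p
  if (length(p) == 1L) p <- stats::setNames(rep(p, length(smp)), smp)
  if (!all(smp %in% names(p))) stop("depth model lacks sample(s): ",
                                    paste(setdiff(smp, names(p)), collapse = ", "))
  p <- p[smp]
  keep <- matrix(runif(length(presence)) < rep(p, times = ncol(presence)),
                 nrow(presence), ncol(presence))
  # read counts: log-normal quantiles assigned by capture-probability rank
  r <- rank(p, ties.method = "first")
  q <- stats::qlnorm((r - 0.5) / length(r), depth$meanlog, depth$sdlog)
  list(presence = presence & keep,
       reads_passing_filter = stats::setNames(round(q), smp))
}

#' Configuration for the synthetic GBS generator
#'
#' Defaults emulate the study design the package targets: 6 species in the
#' fixed transisthmian topology, 4 diploid individuals per species,
#' 90-bp loci, per-locus rate variation (mean-1 Gamma), a 6-bp EcoT22I
#' recognition site driving allelic dropout, and depth-driven missingness.
#'
#' @param model a [demographic_model()].
#' @param n_individuals named integer vector of diploids per species; a
#'   single unnamed value is recycled to all species.
#' @param n_loci number of loci.
#' @param locus_length locus length in bp (reads are ~100 bp with cut sites
#'   trimmed; 90 bp is the package default).
#' @param rate_alpha shape of the mean-1 Gamma for per-locus rate
#'   multipliers, or `"constant"` for `r_l = 1` everywhere.
#' @param site_length recognition-site length in bp.
#' @param dropout enable restriction-site allelic dropout.
#' @param depth a [depth_model()].
#' @param seed RNG seed (determinism contract: same config + seed gives a
#'   byte-identical dataset).
#' @param keep_genealogies store each locus genealogy in the truth table.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(model = transisthmian_model(),
                              n_individuals = 4, n_loci = 1000,
                              locus_length = 90, rate_alpha = 1,
                              site_length = 6, dropout = TRUE,
                              depth = depth_model(), seed = 1,
                              keep_genealogies = FALSE) {
  sp <- model$labels[seq_len(model$n_species)]
  if (is.null(names(n_individuals)) && length(n_individuals) == 1L)
    n_individuals <- stats::setNames(rep(n_individuals, length(sp)), sp)
  stopifnot(all(n_individuals >= 1), n_loci >= 1, locus_length >= 1,
            site_length >= 1)
  if (!identical(rate_alpha, "constant")) stopifnot(rate_alpha > 0)
  structure(list(model = model, n_individuals = n_individuals,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 rate_alpha = rate_alpha, site_length = site_length,
                 dropout = isTRUE(dropout), depth = depth,
                 seed = as.integer(seed),
                 keep_genealogies = isTRUE(keep_genealogies)),
            class = "simulation_config")
}

# IUPAC collapse lookup for integer base pairs (1..4 = ACGT)
.collapse_lut <- local({
  b <- c("A", "C", "G", "T")
  m <- outer(b, b, Vectorize(function(x, y) iupac_code(x, y)))
  as.vector(m)   # index (a-1)*4 + b
})

#' Simulate a full GBS dataset with truth tables
#'
#' Orchestrates the generator: draws per-locus rate multipliers (mean-1
#' Gamma, renormalized so the realized mean is exactly 1), simulates one
#' structured-coalescent genealogy per locus, overlays JC69 mutations,
#' applies restriction-site allelic dropout (an allele lost to a cut-site
#' substitution; a diploid's locus is missing only when both alleles drop,
#' a single surviving allele yielding an apparently homozygous sequence)
#' and depth-driven missingness, then collapses each diploid's haplotype
#' pair into one unphased IUPAC sequence.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `locus_set` (a [locus_set()]) and `truth`
#'   (list: `model`, `rates` data frame of true `r_l`, `dropout` data frame
#'   with one row per (locus, sample, allele) and cause in
#'   `none`/`site_mutation`/`depth`, `genealogies` if requested).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  model <- cfg$model
  sp <- names(cfg$n_individuals)
  sample_ids <- unlist(lapply(sp, function(s)
    paste0(s, "_", seq_len(cfg$n_individuals[[s]]))))
  sample_sp <- rep(sp, cfg$n_individuals)
  nsmp <- length(sample_ids)
  lineages <- stats::setNames(2L * as.integer(cfg$n_individuals), sp)
  tip_labels <- as.vector(rbind(paste0(sample_ids, ".a"),
                                paste0(sample_ids, ".b")))
  tip_labels <- tip_labels[order(rep(match(sample_sp, sp), each = 2))]
  # tips grouped by species to match `lineages`; sample of tip i:
  tip_sample <- sub("\\.[ab]$", "", tip_labels)

  r_l <- if (identical(cfg$rate_alpha, "constant")) rep(1, cfg$n_loci)
         else { x <- rgamma(cfg$n_loci, cfg$rate_alpha, cfg$rate_alpha)
                x / mean(x) }

  p <- cfg$depth$p
  if (length(p) == 1L) p <- stats::setNames(rep(p, nsmp), sample_ids)

  loci <- vector("list", cfg$n_loci)
  presence <- matrix(TRUE, nsmp, cfg$n_loci,
                     dimnames = list(sample_ids, NULL))
  causes <- vector("list", cfg$n_loci)
  gens <- if (cfg$keep_genealogies) vector("list", cfg$n_loci) else NULL
  lut <- .collapse_lut
  base <- c("A", "C", "G", "T")

  for (l in seq_len(cfg$n_loci)) {
    g <- simulate_genealogy(model, lineages, tip_labels)
    haps <- sim_haplotypes_int(g, cfg$locus_length, r_l[l])
    allele_ok <- if (cfg$dropout)
      apply_restriction_dropout(g, cfg$site_length, r_l[l])
    else stats::setNames(rep(TRUE, 2L * nsmp), tip_labels)
    cause <- ifelse(allele_ok, "none", "site_mutation")
    seqs <- character(0)
    for (i in seq_len(nsmp)) {
      a <- 2L * i - 1L; b <- 2L * i
      oka <- allele_ok[[a]]; okb <- allele_ok[[b]]
      if (!oka && !okb) { presence[i, l] <- FALSE; next }
      s <- if (oka && okb) {
        lut[(haps[a, ] - 1L) * 4L + haps[b, ]]
      } else if (oka) base[haps[a, ]] else base[haps[b, ]]
      seqs[tip_sample[a]] <- paste(s, collapse = "")
    }
    loci[[l]] <- list(locus_id = sprintf("L%05d", l), seqs = seqs)
    causes[[l]] <- cause
    if (cfg$keep_genealogies) gens[[l]] <- g
  }

  dm <- apply_depth_missingness(presence, depth_model(p, cfg$depth$meanlog,
                                                      cfg$depth$sdlog))
  lost_depth <- presence & !dm$presence
  presence <- dm$presence

  keep_loci <- which(colSums(presence) > 0)
  out_loci <- vector("list", length(keep_loci))
  for (j in seq_along(keep_loci)) {
    l <- keep_loci[j]
    loc <- loci[[l]]
    loc$seqs <- loc$seqs[names(loc$seqs) %in% sample_ids[presence[, l]]]
    out_loci[[j]] <- loc
  }

  cause_df <- data.frame(
    locus_id = rep(sprintf("L%05d", seq_len(cfg$n_loci)), each = 2L * nsmp),
    sample_id = rep(rep(sample_ids, each = 2L), cfg$n_loci),
    allele = rep(c("a", "b"), nsmp * cfg$n_loci),
    cause = unlist(causes), stringsAsFactors = FALSE)
  dd <- which(lost_depth, arr.ind = TRUE)
  if (nrow(dd)) {
    key <- paste(sprintf("L%05d", dd[, 2]), sample_ids[dd[, 1]])
    hit <- paste(cause_df$locus_id, cause_df$sample_id) %in% key &
      cause_df$cause == "none"
    cause_df$cause[hit] <- "depth"
  }

  samples <- data.frame(sample_id = sample_ids, species_id = sample_sp,
                        reads_passing_filter =
                          as.numeric(dm$reads_passing_filter[sample_ids]),
                        stringsAsFactors = FALSE)
  ls <- locus_set(out_loci, samples,
                  provenance = sprintf("simulate_dataset(seed=%d)", cfg$seed))
  truth <- list(model = model,
                rates = data.frame(locus_id = sprintf("L%05d", seq_len(cfg$n_loci)),
                                   r_l = r_l, stringsAsFactors = FALSE),
                dropout = cause_df, genealogies = gens)
  list(locus_set = ls, truth = truth)
}
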