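#' Locus presence-absence (LPA) matrix
#'
#' Binary samples x loci matrix: entry (i, l) is 1 iff sample i has a
#' sequence (with at least one called base) at locus l.
#'
#' @param ls a `locus_set`.
#' @param exclude sample ids to drop (e.g. a poorly sequenced individual
#'   that would otherwise dominate ordinations).
#' @return integer matrix with sample row names and locus column names.
#' @export
build_lpa <- function(ls, exclude = character()) {
  smp <- setdiff(ls$samples$sample_id, exclude)
  m <- matrix(0L, length(smp), n_loci(ls),
              dimnames = list(smp, locus_ids(ls)))
  for (l in ls$loci) {
    present <- names(l$seqs)[vapply(l$seqs, has_called_base, logical(1))]
    present <- intersect(present, smp)
    m[present, l$locus_id] <- 1L
  }
  m
}

#' Pairwise shared-locus counts and proportions
#'
#' @param lpa binary LPA matrix (samples x loci).
#' @return list of class `shared_locus_summary`: `counts` (symmetric
#'   samples x samples matrix of pairwise shared loci; diagonal =
#'   per-sample locus counts) and `proportions` (counts divided by the
#'   total number of loci scored in the dataset).
#' @export
shared_locus_summary <- function(lpa) {
  counts <- lpa %*% t(lpa)
  structure(list(counts = counts,
                 proportions = counts / ncol(lpa),
                 n_loci = ncol(lpa)),
            class = "shared_locus_summary")
}

#' Pairwise Jaccard distances from an LPA matrix
#'
#' \eqn{d(i,j) = 1 - |L_i \cap L_j| / |L_i \cup L_j|} over each pair's
#' locus sets.
#'
#' @param lpa binary LPA matrix; no all-zero rows allowed.
#' @return symmetric distance matrix with zero diagonal.
#' @export
jaccard_distances <- function(lpa) {
  if (any(rowSums(lpa) == 0))
    stop("all-zero row(s): ",
         paste(rownames(lpa)[rowSums(lpa) == 0], collapse = ", "))
  inter <- lpa %*% t(lpa)
  tot <- rowSums(lpa)
  uni <- outer(tot, tot, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  d
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Kruskal NMDS (stress-1, isotonic regression with tie averaging) via
#' repeated `vegan::monoMDS` runs from random starting configurations; the
#' best-stress solution is reported. Deterministic under `seed`.
#'
#' @param d symmetric distance matrix, zero diagonal.
#' @param K number of ordination axes (`K < n`).
#' @param n_restarts random restarts.
#' @param max_iter,tol iteration cap and convergence tolerance per run.
#' @param seed RNG seed.
#' @return list of class `ordination_result`: `coordinates` (samples x K),
#'   `stress` (Kruskal stress-1 of the best run), `n_restarts`,
#'   `converged`, `seed`, and `stress_all` per restart.
#' @export
nmds <- function(d, K = 3, n_restarts = 50, max_iter = 500, tol = 1e-7,
                 seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (K >= n) stop("K must be smaller than the number of samples")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("d must be symmetric with zero diagonal")
  set.seed(seed)
  best <- NULL
  stress_all <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- matrix(stats::rnorm(n * K), n, K)
    fit <- vegan::monoMDS(stats::as.dist(d), y = init, k = K, model = "global",
                          maxit = max_iter, sfgrmin = tol, sratmax = 1 - 1e-9)
    stress_all[r] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, stress = best$stress,
                 n_restarts = n_restarts,
                 converged = best$maxits == 0 || best$iters < max_iter,
                 seed = seed, stress_all = stress_all),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("NMDS ordination: K =", ncol(x$coordinates),
      " stress =", format(x$stress, digits = 4),
      " (best of", x$n_restarts, "restarts)\n")
  invisible(x)
}

#' Nested linear models of pairwise shared loci
#'
#' Model A predicts the number of loci shared by a sample pair from
#' sequencing effort alone: `shared ~ log10(sqrt(R_i * R_j))` (the log-root
#' product of QC-passing reads). Model B adds the pair's patristic
#' phylogenetic distance. Reported alongside each fit is the nested-model
#' F test; under restriction-site dropout the distance coefficient is
#' expected negative (distant pairs share fewer loci).
#'
#' @param summary a [shared_locus_summary()].
#' @param reads named numeric vector of reads passing filter per sample.
#' @param phylo_d labeled patristic distance matrix between the samples
#'   (tip labels must cover the summary's samples).
#' @return list of class `shared_locus_models`: `fitA`, `fitB` (each with
#'   `coefficients`, `r2`, `df_residual`), `anova` (F and p of the nested
#'   comparison), and the pair-level `data`.
#' @export
fit_shared_locus_models <- function(summary, reads, phylo_d) {
  smp <- rownames(summary$counts)
  reads <- stats::setNames(as.numeric(reads), names(reads))  # avoid int overflow
  if (!all(smp %in% names(reads))) stop("reads missing for some samples")
  if (!all(smp %in% rownames(phylo_d)))
    stop("phylogenetic distances missing for some samples")
  pairs <- which(upper.tri(summary$counts), arr.ind = TRUE)
  df <- data.frame(
    i = smp[pairs[, 1]], j = smp[pairs[, 2]],
    shared = summary$counts[pairs],
    log_root_reads = log10(sqrt(reads[smp[pairs[, 1]]] *
                                reads[smp[pairs[, 2]]])),
    phylo_dist = phylo_d[cbind(smp[pairs[, 1]], smp[pairs[, 2]])],
    stringsAsFactors = FALSE)
  if (stats::sd(df$log_root_reads) == 0)
    stop("constant read predictor; singular design")
  fitA <- stats::lm(shared ~ log_root_reads, data = df)
  fitB <- stats::lm(shared ~ log_root_reads + phylo_dist, data = df)
  an <- stats::anova(fitA, fitB)
  pack <- function(f) list(coefficients = stats::coef(f),
                           r2 = summary(f)$r.squared,
                           df_residual = f$df.residual,
                           fit = f)
  structure(list(fitA = pack(fitA), fitB = pack(fitB),
                 anova = list(F = an$F[2], p = an$`Pr(>F)`[2]),
                 data = df),
            class = "shared_locus_models")
}

#' @export
print.shared_locus_models <- function(x, ...) {
  cat("shared-locus linear models over", nrow(x$data), "sample pairs\n")
  cat(sprintf("  A (reads only):        r2 = %.3f\n", x$fitA$r2))
  cat(sprintf("  B (+ phylo distance):  r2 = %.3f  (beta_dist = %.3g)\n",
              x$fitB$r2, x$fitB$coefficients[["phylo_dist"]]))
  cat(sprintf("  nested F = %.2f, p = %.3g\n", x$anova$F, x$anova$p))
  invisible(x)
}
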