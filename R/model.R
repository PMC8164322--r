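#' Isolation-with-migration demographic model
#'
#' Binds a fixed rooted species topology to mutation-scaled parameters:
#' one population size \eqn{\Theta = 4 N_e \mu} per branch (leaf and
#' ancestral populations, \eqn{2n-1} in total), one divergence time
#' \eqn{\tau} per internal node (expected substitutions per site, measured
#' backward from the present), and optional directional migration bands.
#'
#' @param tree rooted binary species tree (`phylo`, Newick string or file).
#'   Internal node labels name the ancestral populations; unlabeled nodes
#'   are auto-labeled `N<k>` in `ape` node order (root is `root`).
#' @param theta named numeric vector, one positive entry per population
#'   label (all `2n-1`). A single unnamed value is recycled to all.
#' @param tau named numeric vector of divergence times, one per internal
#'   node label; every internal node's time must be smaller than its
#'   parent's.
#' @param bands optional data frame with columns `source`, `target`, `rate`:
#'   forward-in-time migrants move `source -> target` at mutation-scaled
#'   rate \eqn{M = m/\mu}.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(tree, theta, tau, bands = NULL) {
  tree <- as_phylo(tree)
  n <- length(tree$tip.label)
  if (!ape::is.rooted(tree) || tree$Nnode != n - 1L)
    stop("tree must be rooted and binary (", n - 1L, " internal nodes for ",
         n, " tips)")
  labels <- population_labels(tree)
  npop <- 2L * n - 1L
  if (is.null(names(theta)) && length(theta) == 1L)
    theta <- stats::setNames(rep(theta, npop), labels)
  if (!all(labels %in% names(theta)))
    stop("theta missing for population(s): ",
         paste(setdiff(labels, names(theta)), collapse = ", "))
  internal <- labels[(n + 1L):npop]
  if (is.null(names(tau)) && length(tau) == length(internal))
    names(tau) <- internal
  if (!all(internal %in% names(tau)))
    stop("tau missing for internal node(s): ",
         paste(setdiff(internal, names(tau)), collapse = ", "))
  if (any(theta[labels] <= 0)) stop("theta must be positive")
  if (any(tau[internal] < 0)) stop("tau must be nonnegative")

  parent <- integer(npop); parent[] <- NA_integer_
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  tau_full <- numeric(npop)
  tau_full[(n + 1L):npop] <- tau[internal]
  for (v in (n + 1L):npop) {
    if (!is.na(parent[v]) && tau_full[v] >= tau_full[parent[v]])
      stop("tau ordering violated: ", labels[v], " (", tau_full[v],
           ") must predate its parent ", labels[parent[v]],
           " (", tau_full[parent[v]], ")")
  }
  m <- structure(list(tree = tree, labels = labels, theta = theta[labels],
                      tau = tau_full, parent = parent, n_species = n,
                      bands = NULL), class = "demographic_model")
  if (!is.null(bands) && nrow(bands)) {
    for (k in seq_len(nrow(bands))) {
      b <- migration_band(bands$source[k], bands$target[k], bands$rate[k], m)
    }
    m$bands <- data.frame(source = as.character(bands$source),
                          target = as.character(bands$target),
                          rate = as.numeric(bands$rate),
                          stringsAsFactors = FALSE)
  }
  m
}

#' Population labels of a species tree
#'
#' Leaves first (in `ape` tip order), then ancestral populations in `ape`
#' node order; unlabeled internal nodes become `N<k>` and the root `root`.
#'
#' @param tree a rooted `phylo` (or Newick string/file).
#' @return character vector of length `2n-1`.
#' @export
population_labels <- function(tree) {
  tree <- as_phylo(tree)
  n <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab) || !length(lab)) lab <- rep("", tree$Nnode)
  auto <- paste0("N", seq_len(tree$Nnode) + n)
  auto[1] <- "root"
  lab <- ifelse(nzchar(lab), lab, auto)
  c(tree$tip.label, lab)
}

#' Validate a single migration band against a model
#'
#' @param source,target population labels; forward-in-time migrants move
#'   `source -> target`.
#' @param rate mutation-scaled migration rate `M >= 0`.
#' @param model a `demographic_model` (for lifespan-overlap checking).
#' @return a one-row data frame.
#' @export
migration_band <- function(source, target, rate, model = NULL) {
  if (identical(source, target)) stop("migration band source == target")
  if (rate < 0) stop("migration rate must be nonnegative")
  if (!is.null(model)) {
    i <- match(c(source, target), model$labels)
    if (anyNA(i)) stop("unknown population in band: ", source, "->", target)
    sp <- lifespan(model, i[1]); tp <- lifespan(model, i[2])
    if (min(sp[2], tp[2]) <= max(sp[1], tp[1]))
      stop("band populations never coexist: ", source, "->", target)
  }
  data.frame(source = source, target = target, rate = rate,
             stringsAsFactors = FALSE)
}

# lifespan [begin, end) of population index i, backward time
lifespan <- function(model, i) {
  end <- if (is.na(model$parent[i])) Inf else model$tau[model$parent[i]]
  c(model$tau[i], end)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model:", x$n_species, "species,",
      length(x$labels), "populations\n")
  cat("  theta: [", format(min(x$theta), digits = 3), ",",
      format(max(x$theta), digits = 3), "]\n")
  it <- x$tau[(x$n_species + 1L):length(x$tau)]
  cat("  tau:  ", paste(paste0(x$labels[(x$n_species + 1L):length(x$labels)],
                               "=", format(it, digits = 3)), collapse = ", "), "\n")
  if (!is.null(x$bands))
    cat("  bands:", paste(paste0(x$bands$source, "->", x$bands$target,
                                 " (M=", x$bands$rate, ")"), collapse = ", "), "\n")
  invisible(x)
}

# flat arrays for the C++ sampler and the R simulator (0-based indices)
model_arrays <- function(model) {
  npop <- length(model$labels)
  bands <- model$bands
  list(npop = npop,
       n_leaf = model$n_species,
       parent = ifelse(is.na(model$parent), -1L, model$parent - 1L),
       tau = as.numeric(model$tau),
       theta = as.numeric(model$theta),
       band_src = if (is.null(bands)) integer() else match(bands$source, model$labels) - 1L,
       band_tgt = if (is.null(bands)) integer() else match(bands$target, model$labels) - 1L,
       band_rate = if (is.null(bands)) numeric() else as.numeric(bands$rate),
       labels = model$labels)
}

#' Default six-species transisthmian study tree
#'
#' Three sister-species pairs of snapping shrimp separated by the Isthmus of
#' Panama — (wonkimi, malleator), (colombiensis, estuariensis),
#' (panamensis, formosus) — in a fixed rooted topology with labeled
#' ancestral populations. Used as the default topology of the synthetic
#' data generator.
#'
#' @return Newick string.
#' @export
transisthmian_tree <- function() {
  paste0("((wonkimi,malleator)WM,((colombiensis,estuariensis)EC,",
         "(panamensis,formosus)PF)ECPF)root;")
}

#' Default mutation-scaled parameters for the study tree
#'
#' Divergence times of the three pairs sit at the magnitudes the
#' transisthmian calibration implies (5.95e-3, 7.93e-3, 12.5e-3) with
#' deeper ancestral splits, and diversity near \eqn{\Theta \approx 0.02}.
#'
#' @param bands optional migration-band data frame.
#' @return a `demographic_model` on [transisthmian_tree()].
#' @export
transisthmian_model <- function(bands = NULL) {
  theta <- c(wonkimi = 0.018, malleator = 0.018, colombiensis = 0.027,
             estuariensis = 0.027, panamensis = 0.0205, formosus = 0.0205,
             root = 0.02, WM = 0.018, ECPF = 0.02, EC = 0.027, PF = 0.0205)
  tau <- c(WM = 5.95e-3, EC = 7.93e-3, PF = 12.5e-3, ECPF = 0.025,
           root = 0.04)
  demographic_model(transisthmian_tree(), theta, tau, bands)
}
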