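#' Dataset filter specification
#'
#' The study's dataset-naming scheme encodes a cohort plus the m/s filter:
#' `<cohort>m<int>s<int>`, e.g. `Am4s2` = all samples, every locus
#' genotyped in at least 4 individuals and 2 species. Cohort `"A"` means
#' all samples; any other cohort label must be resolved to an explicit
#' sample list via the `cohort_samples` argument of [apply_ms_filter()].
#'
#' @param cohort `"A"` or a character vector of sample ids (or a label to
#'   be resolved later).
#' @param m minimum number of individuals genotyped per locus.
#' @param s minimum number of distinct species per locus.
#' @param max_het_sites per-sequence heterozygosity cap for the paralog
#'   filter (default 8: consensus sequences with more than 8 heterozygous
#'   sites are discarded).
#' @param max_shared_het_samples per-site shared-heterozygote cap (default
#'   2: loci with a site heterozygous in more than 2 samples are discarded).
#' @param neutral_only restrict to putatively neutral loci.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cohort = "A", m = 1L, s = 1L, max_het_sites = 8L,
                        max_shared_het_samples = 2L, neutral_only = FALSE) {
  stopifnot(m >= 1, s >= 1, max_het_sites >= 0, max_shared_het_samples >= 0)
  structure(list(cohort = cohort, m = as.integer(m), s = as.integer(s),
                 max_het_sites = as.integer(max_het_sites),
                 max_shared_het_samples = as.integer(max_shared_het_samples),
                 neutral_only = isTRUE(neutral_only)),
            class = "filter_spec")
}

#' Parse a dataset name into a filter specification
#'
#' @param name dataset name matching `<cohort>m<int>s<int>` (e.g. `"Am4s2"`,
#'   `"23m6s2"`, `"Am3s3"`).
#' @return a [filter_spec()].
#' @export
parse_dataset_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)m([0-9]+)s([0-9]+)$", name))[[1]]
  if (length(m) != 4L || !nzchar(m[2]))
    stop("malformed dataset name (expect <cohort>m<int>s<int>): ", name)
  filter_spec(cohort = m[2], m = as.integer(m[3]), s = as.integer(m[4]))
}

#' Paralog heuristics: heterozygosity caps
#'
#' Two rules target collapsed paralogs: (a) any per-sample consensus
#' sequence with more than `max_het_sites` heterozygous (ambiguity) sites
#' is discarded; then (b) any locus retaining a site at which more than
#' `max_shared_het_samples` samples are heterozygous is discarded whole.
#' Loci left without samples are dropped.
#'
#' @param ls a `locus_set`.
#' @param spec a [filter_spec()] (only the two het thresholds are used).
#' @return filtered `locus_set` with updated provenance.
#' @export
apply_paralog_filters <- function(ls, spec = filter_spec()) {
  het <- names(IUPAC_HET)
  out <- list()
  for (l in ls$loci) {
    chars <- strsplit(l$seqs, "")
    nhet <- vapply(chars, function(x) sum(x %in% het), integer(1))
    keep <- nhet <= spec$max_het_sites
    if (!any(keep)) next
    l$seqs <- l$seqs[keep]; chars <- chars[keep]
    m <- matrix(unlist(chars), nrow = length(chars), byrow = TRUE)
    shared <- colSums(matrix(m %in% het, nrow = nrow(m)))
    if (any(shared > spec$max_shared_het_samples)) next
    out[[length(out) + 1L]] <- l
  }
  locus_set(out, ls$samples,
            c(ls$provenance,
              sprintf("paralog_filters(max_het=%d,max_shared_het=%d)",
                      spec$max_het_sites, spec$max_shared_het_samples)),
            validate = FALSE)
}

#' Minimum-individuals / minimum-species (m/s) dataset filter
#'
#' Restricts the dataset to the cohort's samples, then keeps only loci
#' genotyped in at least `m` individuals of the cohort and at least `s`
#' distinct species. A sample counts as genotyped when it has a sequence
#' with at least one called (non-N) base.
#'
#' @param ls a `locus_set`.
#' @param spec a [filter_spec()] or dataset name string.
#' @param cohort_samples optional character vector resolving a non-`"A"`
#'   cohort label to sample ids.
#' @return filtered `locus_set`.
#' @export
apply_ms_filter <- function(ls, spec, cohort_samples = NULL) {
  if (is.character(spec)) spec <- parse_dataset_name(spec)
  cohort <- if (identical(spec$cohort, "A")) ls$samples$sample_id
            else if (!is.null(cohort_samples)) cohort_samples
            else if (length(spec$cohort) > 1L) spec$cohort
            else stop("cohort '", spec$cohort,
                      "' needs an explicit cohort_samples list")
  if (spec$s > length(unique(ls$samples$species_id[
        ls$samples$sample_id %in% cohort])))
    stop("s exceeds number of species in cohort")
  sp_of <- stats::setNames(ls$samples$species_id, ls$samples$sample_id)
  out <- list()
  for (l in ls$loci) {
    seqs <- l$seqs[names(l$seqs) %in% cohort]
    seqs <- seqs[vapply(seqs, has_called_base, logical(1))]
    if (length(seqs) >= spec$m &&
        length(unique(sp_of[names(seqs)])) >= spec$s) {
      l$seqs <- seqs
      out[[length(out) + 1L]] <- l
    }
  }
  samples <- ls$samples[ls$samples$sample_id %in% cohort, , drop = FALSE]
  locus_set(out, samples,
            c(ls$provenance, sprintf("ms_filter(m=%d,s=%d,cohort=%s)",
                                     spec$m, spec$s,
                                     paste(spec$cohort, collapse = "+"))),
            validate = FALSE)
}

#' Partition loci into putatively neutral and coding sets
#'
#' @param ls a `locus_set`.
#' @param coding_ids locus ids annotated as putatively coding (matches to
#'   mRNA/protein/InterPro databases); unknown ids are reported and
#'   ignored.
#' @return list with `neutral` and `coding` locus_sets (disjoint,
#'   exhaustive).
#' @export
partition_neutral <- function(ls, coding_ids = character()) {
  ids <- locus_ids(ls)
  unknown <- setdiff(coding_ids, ids)
  if (length(unknown))
    warning("ignoring ", length(unknown), " unknown coding id(s): ",
            paste(utils::head(unknown, 5), collapse = ", "))
  is_coding <- ids %in% coding_ids
  list(neutral = locus_set(ls$loci[!is_coding], ls$samples,
                           c(ls$provenance, "partition_neutral:neutral"),
                           validate = FALSE),
       coding = locus_set(ls$loci[is_coding], ls$samples,
                          c(ls$provenance, "partition_neutral:coding"),
                          validate = FALSE))
}

#' Extract SNPs from a locus_set
#'
#' One row per variable site. Ambiguity codes expand to two alleles for
#' that sample; any other non-ACGT character (N) leaves the sample
#' ungenotyped at that site. A site is a SNP when at least two distinct
#' alleles segregate among genotyped samples.
#'
#' @param ls a `locus_set`.
#' @return object of class `snp_table`: data frame `sites` (columns
#'   `locus_id`, `site` 0-based, `alleles` slash-joined, `n_alleles`,
#'   `biallelic`) and character matrix `gt` (rows = SNPs, columns = all
#'   samples, entries like `"A/G"`, `NA` when ungenotyped).
#' @export
extract_snps <- function(ls) {
  smp <- ls$samples$sample_id
  rows <- list(); gts <- list()
  for (l in ls$loci) {
    chars <- strsplit(l$seqs, "")
    m <- matrix(unlist(chars), nrow = length(chars), byrow = TRUE,
                dimnames = list(names(l$seqs), NULL))
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      pairs <- lapply(col, iupac_alleles)
      ok <- !vapply(pairs, is.null, logical(1))
      if (!any(ok)) next
      alleles <- sort(unique(unlist(pairs[ok])))
      if (length(alleles) < 2L) next
      gt <- rep(NA_character_, length(smp))
      names(gt) <- smp
      gt[names(col)[ok]] <- vapply(pairs[ok], function(p)
        paste(sort(p), collapse = "/"), character(1))
      rows[[length(rows) + 1L]] <-
        data.frame(locus_id = l$locus_id, site = j - 1L,
                   alleles = paste(alleles, collapse = "/"),
                   n_alleles = length(alleles),
                   biallelic = length(alleles) == 2L,
                   stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- gt
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows)
           else data.frame(locus_id = character(), site = integer(),
                           alleles = character(), n_alleles = integer(),
                           biallelic = logical(), stringsAsFactors = FALSE)
  gt <- if (length(gts)) do.call(rbind, gts)
        else matrix(NA_character_, 0, length(smp), dimnames = list(NULL, smp))
  structure(list(sites = sites, gt = gt, samples = smp), class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", nrow(x$sites), "SNPs (",
      sum(x$sites$biallelic), "biallelic ) across",
      length(unique(x$sites$locus_id)), "loci\n")
  invisible(x)
}

#' Transition/transversion ratio of biallelic SNPs
#'
#' Transitions are the allele sets \{A,G\} and \{C,T\}; everything else
#' among the biallelic SNPs is a transversion. Multi-allelic rows are
#' excluded (the convention of common VCF tooling).
#'
#' @param snps a `snp_table`.
#' @return Ts/Tv as a single number; `Inf` with a warning when no
#'   transversions are present.
#' @export
ts_tv_ratio <- function(snps) {
  al <- snps$sites$alleles[snps$sites$biallelic]
  if (!length(al)) stop("no biallelic SNPs")
  ts <- sum(al %in% c("A/G", "C/T"))
  tv <- length(al) - ts
  if (tv == 0L) { warning("zero transversions; Ts/Tv is infinite"); return(Inf) }
  ts / tv
}

#' Six-type unpolarized substitution spectrum
#'
#' Counts biallelic SNPs by unordered allele pair — \{A,C\}, \{A,G\},
#' \{A,T\}, \{C,G\}, \{C,T\}, \{G,T\} — with proportions.
#'
#' @param snps a `snp_table`.
#' @return data frame with columns `pair`, `count`, `proportion`.
#' @export
substitution_spectrum <- function(snps) {
  pairs <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")
  al <- snps$sites$alleles[snps$sites$biallelic]
  counts <- vapply(pairs, function(p) sum(al == p), numeric(1))
  data.frame(pair = pairs, count = counts,
             proportion = if (sum(counts) > 0) counts / sum(counts)
                          else rep(0, 6),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Random locus subsets for replicate analyses
#'
#' Draws `k` subsets of `size` loci, each without replacement within the
#' subset but independently of the others (loci may recur across subsets),
#' mirroring replicate random reductions of a dataset too large to analyze
#' whole.
#'
#' @param ls a `locus_set`.
#' @param k number of subsets.
#' @param size loci per subset.
#' @param seed RNG seed (subsets are deterministic under it).
#' @return list of `k` locus_sets.
#' @export
random_subsets <- function(ls, k, size, seed = 1) {
  if (size > n_loci(ls)) stop("size (", size, ") exceeds locus count (",
                              n_loci(ls), ")")
  set.seed(seed)
  ids <- locus_ids(ls)
  lapply(seq_len(k), function(i)
    subset_loci(ls, sample(ids, size),
                note = sprintf("random_subset(%d/%d,size=%d,seed=%d)",
                               i, k, size, seed)))
}

#' Export a snp_table as a minimal VCF
#'
#' CHROM = locus id, POS = site + 1, unphased GT, no QUAL/FILTER/INFO
#' content beyond placeholders.
#'
#' @param snps a `snp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", snps$samples), collapse = "\t")), con)
  for (i in seq_len(nrow(snps$sites))) {
    al <- strsplit(snps$sites$alleles[i], "/")[[1]]
    ref <- al[1]; alt <- al[-1]
    code <- function(g) {
      if (is.na(g)) return("./.")
      paste(match(strsplit(g, "/")[[1]], al) - 1L, collapse = "/")
    }
    writeLines(paste(c(snps$sites$locus_id[i], snps$sites$site[i] + 1L, ".",
                       ref, paste(alt, collapse = ","), ".", "PASS", ".",
                       "GT", vapply(snps$gt[i, ], code, character(1))),
                     collapse = "\t"), con)
  }
  invisible(path)
}
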