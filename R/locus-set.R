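#' Multi-sample, multi-locus alignment container
#'
#' A `locus_set` bundles assembled GBS loci: per-locus unphased alignments
#' (heterozygous sites encoded as IUPAC two-base ambiguity codes), a sample
#' table carrying the sample-to-species map, and a free-text provenance
#' record of the filters applied so far.
#'
#' @param loci list of loci; each locus is a list with elements `locus_id`
#'   (string) and `seqs` (named character vector, `sample_id -> sequence`;
#'   absent samples are simply absent from the vector).
#' @param samples data frame with columns `sample_id`, `species_id` and
#'   optionally `reads_passing_filter`; defaults to the samples observed in
#'   `loci` with species `NA`.
#' @param provenance character vector of free-text filter records.
#' @param validate check invariants (identical sequence lengths within a
#'   locus, known alphabet, unique ids).
#'
#' @return an object of class `locus_set`.
#' @export
locus_set <- function(loci = list(), samples = NULL, provenance = character(),
                      validate = TRUE) {
  if (is.null(samples)) {
    ids <- unique(unlist(lapply(loci, function(l) names(l$seqs)), use.names = FALSE))
    samples <- data.frame(sample_id = as.character(ids %||% character()),
                          species_id = rep(NA_character_, length(ids)),
                          reads_passing_filter = rep(NA_real_, length(ids)),
                          stringsAsFactors = FALSE)
  }
  if (is.null(samples$reads_passing_filter))
    samples$reads_passing_filter <- NA_real_
  ls <- structure(list(samples = samples, loci = loci,
                       provenance = as.character(provenance)),
                  class = "locus_set")
  if (validate) validate_locus_set(ls)
  ls
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Validate a locus_set's invariants
#'
#' Checks sequence-length agreement within each locus, the IUPAC alphabet,
#' uniqueness of locus and sample ids, and that every sample appearing in a
#' locus is listed in the sample table.
#'
#' @param ls a `locus_set`.
#' @return `ls`, invisibly; stops with an informative error otherwise.
#' @export
validate_locus_set <- function(ls) {
  stopifnot(inherits(ls, "locus_set"))
  if (anyDuplicated(ls$samples$sample_id))
    stop("duplicated sample_id in samples table")
  ids <- vapply(ls$loci, function(l) l$locus_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated locus_id: ",
                               ids[duplicated(ids)][1])
  for (l in ls$loci) {
    if (length(l$seqs) < 1L)
      stop("locus ", l$locus_id, ": no samples present")
    lens <- nchar(l$seqs)
    if (length(unique(lens)) != 1L)
      stop("locus ", l$locus_id, ": unequal sequence lengths (",
           paste(unique(lens), collapse = ", "), ")")
    bad <- setdiff(unique(strsplit(paste(l$seqs, collapse = ""), "")[[1]]),
                   IUPAC_ALPHABET)
    if (length(bad))
      stop("locus ", l$locus_id, ": illegal characters: ",
           paste(bad, collapse = ""))
    unknown <- setdiff(names(l$seqs), ls$samples$sample_id)
    if (length(unknown))
      stop("locus ", l$locus_id, ": sample(s) not in samples table: ",
           paste(unknown, collapse = ", "))
  }
  invisible(ls)
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", length(x$loci), "loci,", nrow(x$samples), "samples\n")
  sp <- unique(x$samples$species_id)
  cat("  species:", paste(sp[!is.na(sp)], collapse = ", "), "\n")
  if (length(x$loci)) {
    lens <- vapply(x$loci, function(l) nchar(l$seqs[[1]]), numeric(1))
    cat("  locus length:", min(lens), "-", max(lens), "bp\n")
  }
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Number of loci in a locus_set
#' @param ls a `locus_set`.
#' @return integer count.
#' @export
n_loci <- function(ls) length(ls$loci)

#' Locus identifiers of a locus_set
#' @param ls a `locus_set`.
#' @return character vector of locus ids, in storage order.
#' @export
locus_ids <- function(ls) vapply(ls$loci, function(l) l$locus_id, character(1))

#' Subset a locus_set by locus id
#'
#' @param ls a `locus_set`.
#' @param ids locus ids to keep (order taken from `ids`).
#' @param note provenance note appended to the result.
#' @return a `locus_set` with the selected loci.
#' @export
subset_loci <- function(ls, ids, note = NULL) {
  keep <- match(ids, locus_ids(ls))
  if (anyNA(keep)) stop("unknown locus id(s): ",
                        paste(ids[is.na(keep)], collapse = ", "))
  locus_set(ls$loci[keep], ls$samples,
            c(ls$provenance, note %||% character()), validate = FALSE)
}

# number of heterozygous (two-base ambiguity) characters per sequence
count_het_sites <- function(seq) {
  sum(strsplit(seq, "")[[1]] %in% names(IUPAC_HET))
}

# TRUE if the sequence carries any called base (not entirely N)
has_called_base <- function(seq) {
  any(strsplit(seq, "")[[1]] != "N")
}
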