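#' Read assembled loci from disk
#'
#' Supports two text dialects. `"pyrad_loci"` is the pyRAD-style `.loci`
#' layout: blocks of `sampleID<whitespace>sequence` lines, each block closed
#' by a separator line starting with `//` (anything after the `//`,
#' including position-annotation characters, is ignored; a trailing
#' `|locus_id|` tag, if present, names the locus). `"per_locus_fasta"` is a
#' FASTA file with one record per (sample, locus), header
#' `>sample_id locus_id`, consecutive records of one locus grouped.
#'
#' @param path path to the input file.
#' @param dialect `"pyrad_loci"` or `"per_locus_fasta"`.
#' @param samples optional samples table (see [read_samples_table()]) giving
#'   the sample-to-species map; defaults to the observed sample ids.
#' @return a [locus_set()].
#' @export
read_loci <- function(path, dialect = c("pyrad_loci", "per_locus_fasta"),
                      samples = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  loci <- if (dialect == "pyrad_loci") parse_pyrad(lines) else parse_plf(lines)
  ls <- locus_set(loci, provenance = paste0("read_loci(", dialect, ")"))
  if (!is.null(samples)) ls <- attach_samples(ls, samples)
  ls
}

parse_pyrad <- function(lines) {
  loci <- list()
  block <- character()
  auto <- 0L
  for (ln in lines) {
    if (startsWith(trimws(ln), "//")) {
      auto <- auto + 1L
      id <- sub("^.*\\|([^|]+)\\|\\s*$", "\\1", ln)
      if (identical(id, ln)) id <- paste0("L", auto)
      else if (grepl("^[0-9]+$", id)) id <- paste0("L", id)  # pyRAD numbers loci
      loci[[length(loci) + 1L]] <- finish_block(block, id)
      block <- character()
    } else block <- c(block, ln)
  }
  if (length(block)) {
    auto <- auto + 1L
    loci[[length(loci) + 1L]] <- finish_block(block, paste0("L", auto))
  }
  loci
}

finish_block <- function(block, id) {
  if (!length(block)) stop("empty locus block before separator for ", id)
  m <- regmatches(block, regexec("^>?(\\S+)\\s+(\\S+)\\s*$", block))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("locus ", id, ": malformed line: ", block[bad][1])
  ids <- vapply(m, `[`, character(1), 2L)
  seqs <- toupper(vapply(m, `[`, character(1), 3L))
  names(seqs) <- ids
  if (anyDuplicated(ids)) stop("locus ", id, ": duplicated sample ", ids[duplicated(ids)][1])
  if (length(unique(nchar(seqs))) != 1L)
    stop("locus ", id, ": unequal sequence lengths")
  list(locus_id = id, seqs = seqs)
}

parse_plf <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(lines) && !length(hdr)) stop("not FASTA: no '>' headers")
  loci <- list()
  cur_id <- NULL; seqs <- character()
  flush_locus <- function() {
    if (!is.null(cur_id)) {
      if (length(unique(nchar(seqs))) > 1L)
        stop("locus ", cur_id, ": unequal sequence lengths")
      loci[[length(loci) + 1L]] <<- list(locus_id = cur_id, seqs = seqs)
    }
  }
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) stop("malformed FASTA near: ", lines[i])
    parts <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    if (length(parts) < 2L) stop("FASTA header lacks locus id: ", lines[i])
    sid <- parts[1]; lid <- parts[2]
    j <- i + 1L
    sq <- character()
    while (j <= length(lines) && !startsWith(lines[j], ">")) {
      sq <- c(sq, lines[j]); j <- j + 1L
    }
    sq <- toupper(paste(sq, collapse = ""))
    if (!identical(lid, cur_id)) { flush_locus(); cur_id <- lid; seqs <- character() }
    seqs[sid] <- sq
    i <- j
  }
  flush_locus()
  loci
}

#' Write a locus_set to disk
#'
#' Inverse of [read_loci()]: `read_loci(write_loci(ls, p, d), d)` restores
#' sequence content, sample membership and locus order exactly.
#'
#' @param ls a `locus_set`.
#' @param path output file path.
#' @param dialect `"pyrad_loci"` or `"per_locus_fasta"`.
#' @return `path`, invisibly.
#' @export
write_loci <- function(ls, path, dialect = c("pyrad_loci", "per_locus_fasta")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w"); on.exit(close(con))
  for (l in ls$loci) {
    if (dialect == "pyrad_loci") {
      writeLines(paste0(names(l$seqs), "   ", unname(l$seqs)), con)
      writeLines(paste0("//", strrep(" ", max(1L, nchar(l$seqs[[1]]) - 1L)),
                        "|", l$locus_id, "|"), con)
    } else {
      writeLines(paste0(">", names(l$seqs), " ", l$locus_id, "\n",
                        unname(l$seqs)), con)
    }
  }
  invisible(path)
}

#' Read a two/three-column samples table
#'
#' Tab-separated, with header: `sample_id`, `species_id`, optional
#' `reads_passing_filter`.
#'
#' @param path path to the TSV.
#' @return data frame suitable for [locus_set()] / [attach_samples()].
#' @export
read_samples_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = NA)
  need <- c("sample_id", "species_id")
  if (!all(need %in% names(df)))
    stop("samples table must have columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$species_id <- as.character(df$species_id)
  df
}

#' Attach a sample-to-species map to a locus_set
#'
#' @param ls a `locus_set`.
#' @param samples samples data frame or path to a samples TSV.
#' @return the `locus_set` with its sample table replaced.
#' @export
attach_samples <- function(ls, samples) {
  if (is.character(samples)) samples <- read_samples_table(samples)
  seen <- unique(unlist(lapply(ls$loci, function(l) names(l$seqs)), use.names = FALSE))
  missing <- setdiff(seen, samples$sample_id)
  if (length(missing))
    stop("samples table lacks observed sample(s): ", paste(missing, collapse = ", "))
  locus_set(ls$loci, samples, ls$provenance, validate = FALSE)
}

#' Export a locus_set in the G-PhoCS sequence-file layout
#'
#' First line is the locus count; each locus contributes a header line
#' `locus_id n_samples length` followed by one `sampleID sequence` line per
#' present sample. This is the input layout of the external IM-coalescent
#' sampler the package's MCMC mirrors, enabling direct cross-checks.
#'
#' @param ls a `locus_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_gphocs_seqfile <- function(ls, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(length(ls$loci)), con)
  for (l in ls$loci) {
    writeLines(paste(l$locus_id, length(l$seqs), nchar(l$seqs[[1]])), con)
    writeLines(paste(names(l$seqs), unname(l$seqs)), con)
  }
  invisible(path)
}

#' Read a G-PhoCS-layout sequence file
#'
#' Companion reader for [export_gphocs_seqfile()].
#'
#' @param path input file path.
#' @param samples optional samples table.
#' @return a [locus_set()].
#' @export
read_gphocs_seqfile <- function(path, samples = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(lines[1])
  i <- 2L
  loci <- vector("list", n)
  for (k in seq_len(n)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    ns <- as.integer(hdr[2])
    rows <- lines[(i + 1L):(i + ns)]
    m <- strsplit(trimws(rows), "\\s+")
    seqs <- toupper(vapply(m, `[`, character(1), 2L))
    names(seqs) <- vapply(m, `[`, character(1), 1L)
    loci[[k]] <- list(locus_id = hdr[1], seqs = seqs)
    i <- i + ns + 1L
  }
  ls <- locus_set(loci, provenance = "read_gphocs_seqfile")
  if (!is.null(samples)) ls <- attach_samples(ls, samples)
  ls
}

#' Patristic (tip-to-tip path length) distances on a tree
#'
#' @param tree an `ape` `phylo` object, a Newick string, or a path to a
#'   Newick file. All branch lengths must be present and nonnegative.
#' @return labeled symmetric matrix of path lengths; zero diagonal.
#' @export
patristic_distances <- function(tree) {
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

# coerce newick string / file path / phylo to phylo
as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (grepl("\\(", tree)) return(ape::read.tree(text = tree))
    if (file.exists(tree)) return(ape::read.tree(tree))
  }
  stop("cannot interpret tree input")
}

#' Write / read a labeled numeric matrix as TSV
#'
#' Row and column labels are preserved; values round-trip at 15 significant
#' digits.
#'
#' @param m labeled numeric matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% as.character(seq_len(nrow(m))),
                   format(m, digits = 15, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(m) %||% as.character(seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
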