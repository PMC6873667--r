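#' Read assembled contigs from a FASTA file
#'
#' Contigs are returned as a named [Biostrings::DNAStringSet] in file order,
#' uppercased. Only the characters `A`, `C`, `G`, `T` and `N` are accepted;
#' ids must be unique and non-empty.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per FASTA record.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path))
    pb_stop("pb_missing_file", "FASTA file not found: %s", path)
  # readDNAStringSet silently drops letters outside the IUPAC alphabet with
  # a warning; promote that to the illegal-character error
  x <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        pb_stop("pb_illegal_chars",
                "illegal characters (outside A/C/G/T/N) in %s", path)
      invokeRestart("muffleWarning")
    })
  validate_contigs(x, source = path)
}

# shared validation for contig sets built in memory or read from disk
validate_contigs <- function(x, source = "input") {
  if (length(x) == 0L)
    pb_stop("pb_empty_input", "empty input: no sequences in %s", source)
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    pb_stop("pb_missing_id", "every contig must have a non-empty id (%s)", source)
  # FASTA headers may carry descriptions after whitespace; the id is the
  # first token, matching common assembler output
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    pb_stop("pb_duplicate_id", "duplicate id in %s: %s", source,
            ids[duplicated(ids)][1L])
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  bad <- Biostrings::alphabetFrequency(x)
  legal <- c("A", "C", "G", "T", "N")
  extra <- rowSums(bad[, setdiff(colnames(bad), legal), drop = FALSE])
  if (any(extra > 0))
    pb_stop("pb_illegal_chars",
            "illegal characters (outside A/C/G/T/N) in contig %s",
            ids[which(extra > 0)[1L]])
  if (any(Biostrings::width(x) < 1L))
    pb_stop("pb_empty_input", "zero-length sequence in %s", source)
  x
}

#' Write contigs to a FASTA file
#'
#' @param contigs A named `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contigs <- function(contigs, path) {
  Biostrings::writeXStringSet(contigs, path, width = 70L)
  invisible(path)
}

#' Read a per-contig, per-sample coverage table
#'
#' The table is tab-separated with a header `contig_id<TAB><sample>...` and
#' one numeric column per sample, as produced by standard depth-computation
#' workflows. Rows are reordered to match `contigs`; ids present in only one
#' of the two inputs are an error.
#'
#' @param path Path to the TSV file.
#' @param contigs Optional `DNAStringSet`; when given, rows are checked and
#'   reordered against its names.
#' @return A numeric matrix with contig ids as rownames and sample ids as
#'   colnames.
#' @export
read_coverage <- function(path, contigs = NULL) {
  if (!file.exists(path))
    pb_stop("pb_missing_file", "coverage table not found: %s", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    pb_stop("pb_bad_table", "coverage table needs an id column and >=1 sample column")
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    pb_stop("pb_nonnumeric_coverage", "non-numeric coverage value in %s", path)
  storage.mode(vals) <- "double"
  if (anyNA(vals))
    pb_stop("pb_nonnumeric_coverage", "missing/non-numeric coverage value in %s", path)
  if (any(vals < 0))
    pb_stop("pb_negative_coverage", "negative coverage for contig %s",
            ids[which(rowSums(vals < 0) > 0)[1L]])
  rownames(vals) <- ids
  if (!is.null(contigs)) {
    want <- names(contigs)
    if (anyDuplicated(ids))
      pb_stop("pb_duplicate_id", "duplicate contig id in coverage table")
    missing_cov <- setdiff(want, ids)
    missing_fa  <- setdiff(ids, want)
    if (length(missing_cov) || length(missing_fa))
      pb_stop("pb_coverage_mismatch",
              "coverage/contig mismatch: %d contig(s) without coverage, %d coverage row(s) without contig",
              length(missing_cov), length(missing_fa))
    vals <- vals[want, , drop = FALSE]
  }
  vals
}

#' Write a coverage matrix as a TSV table
#'
#' @param coverage Numeric matrix with contig ids as rownames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage <- function(coverage, path) {
  df <- data.frame(contig_id = rownames(coverage), coverage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cut long contigs into fixed-size fragments
#'
#' Standard preprocessing that mitigates local assembly errors: contigs at
#' least twice `chunk_len` long are split into consecutive non-overlapping
#' `chunk_len` fragments, with any final remainder shorter than `chunk_len`
#' merged into the last fragment. Every fragment emitted from a split contig
#' therefore has length in `[chunk_len, 2*chunk_len)`. Shorter contigs pass
#' through intact. Fragment ids are `<parent id>.<i>` with a 0-based index.
#'
#' @param contigs A named `DNAStringSet`.
#' @param chunk_len Fragment length in bp (default 10000).
#' @return A `DNAStringSet` of fragments; total base count equals the input.
#' @export
cut_up_contigs <- function(contigs, chunk_len = 10000L) {
  chunk_len <- as.integer(chunk_len)
  stopifnot(chunk_len >= 1L)
  lens <- Biostrings::width(contigs)
  out_seq <- character(0)
  out_id <- character(0)
  for (i in seq_along(contigs)) {
    L <- lens[i]
    if (L < 2L * chunk_len) {
      out_seq <- c(out_seq, as.character(contigs[[i]]))
      out_id <- c(out_id, names(contigs)[i])
    } else {
      n_frag <- L %/% chunk_len            # remainder merges into last piece
      starts <- (seq_len(n_frag) - 1L) * chunk_len + 1L
      ends <- c(starts[-1L] - 1L, L)
      s <- as.character(contigs[[i]])
      out_seq <- c(out_seq, substring(s, starts, ends))
      out_id <- c(out_id, paste0(names(contigs)[i], ".", seq_len(n_frag) - 1L))
    }
  }
  Biostrings::DNAStringSet(setNames(out_seq, out_id))
}

#' Construct a binning result
#'
#' @param contig_ids Character vector of contig ids.
#' @param bin_labels Integer vector of bin labels in `1..num_bins`.
#' @param num_bins Number of bins (defaults to the number of distinct labels).
#' @param report Optional named list of run metadata.
#' @return An object of class `phasebin_binning`.
#' @export
binning <- function(contig_ids, bin_labels, num_bins = length(unique(bin_labels)),
                    report = list()) {
  stopifnot(length(contig_ids) == length(bin_labels))
  bin_labels <- as.integer(bin_labels)
  if (length(bin_labels) && (any(bin_labels < 1L) || any(bin_labels > num_bins)))
    pb_stop("pb_bad_labels", "bin labels must lie in 1..num_bins")
  if (anyDuplicated(contig_ids))
    pb_stop("pb_duplicate_id", "duplicate contig id in binning result")
  structure(list(contig_ids = as.character(contig_ids),
                 bin_labels = bin_labels,
                 num_bins = as.integer(num_bins),
                 report = report),
            class = "phasebin_binning")
}

#' @export
print.phasebin_binning <- function(x, ...) {
  cat(sprintf("phasebin binning: %d contigs in %d bins\n",
              length(x$contig_ids), x$num_bins))
  sizes <- table(factor(x$bin_labels, levels = seq_len(x$num_bins)))
  cat("bin sizes:", paste(as.integer(sizes), collapse = " "), "\n")
  if (length(x$report)) {
    r <- x$report
    for (nm in names(r))
      if (is.atomic(r[[nm]]) && length(r[[nm]]) == 1L)
        cat(sprintf("  %s: %s\n", nm, format(r[[nm]])))
  }
  invisible(x)
}

#' Write or read a binning as a two-column TSV
#'
#' The file has a header `contig_id<TAB>bin_id` and one row per contig in
#' the original contig order; a round-trip reproduces labels exactly.
#'
#' @param x A `phasebin_binning`.
#' @param path Output (or input) path.
#' @return `write_binning` returns `path` invisibly; `read_binning` returns
#'   a `phasebin_binning`.
#' @export
write_binning <- function(x, path) {
  stopifnot(inherits(x, "phasebin_binning"))
  df <- data.frame(contig_id = x$contig_ids, bin_id = x$bin_labels,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binning
#' @export
read_binning <- function(path) {
  if (!file.exists(path))
    pb_stop("pb_missing_file", "binning file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(binning(character(0), integer(0), num_bins = 0L))
  binning(df$contig_id, df$bin_id, num_bins = max(df$bin_id))
}

#' Read a ground-truth contig-to-species table
#'
#' @param path TSV with columns `contig_id` and `species_label` (header
#'   required; any column names are accepted, the first two columns are used).
#' @return A named character vector mapping contig id to species label.
#' @export
read_truth <- function(path) {
  if (!file.exists(path))
    pb_stop("pb_missing_file", "truth table not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    pb_stop("pb_bad_table", "truth table needs contig id and species columns")
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
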