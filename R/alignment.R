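#' Nucleotide alignments with compressed site patterns
#'
#' A `bets_alignment` stores a nucleotide alignment as its distinct site
#' patterns (columns) with integer multiplicities, the representation the
#' likelihood engine consumes. States are coded 1..4 for A, C, G, T; gaps and
#' ambiguity codes are treated as fully missing (`NA`), contributing partial
#' likelihood 1 for every state under the pruning algorithm. Four
#' "augmentation" counts record invariant A/C/G/T columns added to correct
#' for ascertainment bias in SNP-only alignments (see
#' [augment_constant_sites()]).
#'
#' @param x Character matrix of sequences (rows = taxa, rownames = labels)
#'   over `a,c,g,t` (case-insensitive); anything else is treated as missing.
#' @return An object of class `bets_alignment` with fields `tip.label`,
#'   `patterns` (integer matrix taxa x patterns), `weights`, `aug_counts`.
#' @seealso [read_fasta()], [decompress_alignment()]
#' @export
bets_alignment <- function(x) {
  if (is.null(rownames(x))) stop_betsig("sequence matrix needs taxon rownames",
                                        "betsig_format_error")
  codes <- matrix(match(toupper(x), c("A", "C", "G", "T")),
                  nrow = nrow(x), dimnames = dimnames(x))
  compress_patterns(codes)
}

compress_patterns <- function(codes, aug_counts = c(A = 0, C = 0, G = 0, T = 0)) {
  key <- apply(codes, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  structure(
    list(
      tip.label = rownames(codes),
      patterns = codes[, first, drop = FALSE],
      weights = w,
      aug_counts = aug_counts
    ),
    class = "bets_alignment"
  )
}

#' @export
print.bets_alignment <- function(x, ...) {
  cat(sprintf("<bets_alignment> %d taxa | %d sites | %d unique site patterns\n",
              length(x$tip.label), n_sites(x), length(x$weights)))
  invisible(x)
}

#' Number of sites and patterns in an alignment
#'
#' `n_sites()` counts alignment columns (the sum of pattern weights,
#' including any constant-site augmentation); `n_patterns()` counts distinct
#' site patterns.
#'
#' @param aln A [bets_alignment()].
#' @return An integer scalar.
#' @export
n_sites <- function(aln) as.integer(round(sum(aln$weights)))

#' @rdname n_sites
#' @export
n_patterns <- function(aln) length(aln$weights)

#' Expand compressed site patterns back to a full character matrix
#'
#' Each pattern is repeated according to its weight, so the column multiset
#' of the result equals that of the original alignment (column order is the
#' order of first occurrence, not the original order).
#'
#' @param aln A [bets_alignment()].
#' @return Character matrix of `A/C/G/T/N` (missing as `N`).
#' @export
decompress_alignment <- function(aln) {
  idx <- rep(seq_along(aln$weights), times = round(aln$weights))
  m <- aln$patterns[, idx, drop = FALSE]
  out <- matrix(c("A", "C", "G", "T")[m], nrow = nrow(m))
  out[is.na(out)] <- "N"
  rownames(out) <- aln$tip.label
  out
}

#' Read an alignment from a FASTA file
#'
#' Sequences must be equal-length nucleotide data; labels must be unique.
#' Gaps and IUPAC ambiguity codes become missing characters.
#'
#' @param path Path to a FASTA file.
#' @return A [bets_alignment()], taxa in file order.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 1L) stop_betsig("empty FASTA file", "betsig_format_error")
  if (anyDuplicated(names(dna))) {
    stop_betsig("duplicate sequence labels in FASTA", "betsig_format_error")
  }
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    stop_betsig("ragged FASTA: sequences have unequal lengths", "betsig_format_error")
  }
  m <- toupper(as.character(as.matrix(dna)))
  bets_alignment(m)
}

#' Write an alignment to a FASTA file
#'
#' @param aln A [bets_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  m <- decompress_alignment(aln)
  lines <- character(2L * nrow(m))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  lines[c(FALSE, TRUE)] <- apply(m, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Add invariant columns to correct SNP ascertainment bias
#'
#' Alignments of variable sites only (SNP matrices) overstate divergence
#' unless the likelihood accounts for the invariant positions of the genome.
#' This adds (or increments) four invariant patterns - all-A, all-C, all-G,
#' all-T - with the supplied counts, so the likelihood equals that of the
#' explicit full alignment containing those columns.
#'
#' @param aln A [bets_alignment()].
#' @param counts Numeric vector of 4 non-negative counts (A, C, G, T order).
#' @return A new [bets_alignment()] with updated patterns and weights.
#' @export
augment_constant_sites <- function(aln, counts) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  ntax <- length(aln$tip.label)
  patterns <- aln$patterns
  weights <- aln$weights
  for (s in 1:4) {
    if (counts[s] == 0) next
    col <- rep.int(s, ntax)
    hit <- which(colSums(patterns == col, na.rm = TRUE) == ntax &
                   colSums(is.na(patterns)) == 0L)
    if (length(hit) >= 1L) {
      weights[hit[1L]] <- weights[hit[1L]] + counts[s]
    } else {
      patterns <- cbind(patterns, col)
      weights <- c(weights, counts[s])
    }
  }
  colnames(patterns) <- NULL
  structure(
    list(tip.label = aln$tip.label, patterns = patterns, weights = weights,
         aug_counts = aln$aug_counts + setNames(counts, c("A", "C", "G", "T"))),
    class = "bets_alignment"
  )
}

#' Convert sampling times to tip ages
#'
#' Ages are measured backward from the most recent sample. In the `"times"`
#' dialect the input is calendar-like times (larger = more recent) and ages
#' are `max(time) - time`; in the `"ages"` dialect values are already ages
#' before the present and are used as given.
#'
#' @param dates A data frame with columns `taxon` and `time` (or `age`), or a
#'   named numeric vector.
#' @param taxa Optional character vector of required taxa; an error is raised
#'   if any is missing from `dates`.
#' @param dialect `"times"` (default) or `"ages"`.
#' @return Named numeric vector of ages, youngest tip at 0.
#' @export
parse_dates <- function(dates, taxa = NULL, dialect = c("times", "ages")) {
  dialect <- match.arg(dialect)
  if (is.data.frame(dates)) {
    val_col <- intersect(c("time", "age", "date"), names(dates))[1]
    if (is.na(val_col) || !"taxon" %in% names(dates)) {
      stop_betsig("date table needs columns `taxon` and `time` (or `age`)",
                  "betsig_config_error")
    }
    v <- setNames(as.numeric(dates[[val_col]]), as.character(dates$taxon))
  } else {
    v <- dates
  }
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    stop_betsig("dates must be named by taxon", "betsig_config_error")
  }
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, names(v))
    if (length(missing)) {
      stop_betsig(paste0("no date for taxa: ", paste(missing, collapse = ", ")),
                  "betsig_config_error")
    }
    v <- v[taxa]
  }
  ages <- if (dialect == "times") max(v) - v else v
  if (any(ages < 0)) stop_betsig("negative tip ages", "betsig_config_error")
  ages
}

#' Read a tab-separated date table
#'
#' Expects two columns, `taxon<TAB>time`, with a header row.
#'
#' @inheritParams parse_dates
#' @param path File path.
#' @return Named numeric vector of tip ages (see [parse_dates()]).
#' @export
read_dates <- function(path, taxa = NULL, dialect = c("times", "ages")) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("taxon", "time")
  parse_dates(tab, taxa = taxa, dialect = match.arg(dialect))
}
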