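#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide alphabet, including gap. Ambiguity codes map to the set
# of unambiguous bases they cover.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ALPHABET <- c(names(IUPAC_SETS), "-")
BASES <- c("A", "C", "G", "T")

# Reverse map: sorted base set -> minimal IUPAC code
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  names(codes)[match(key, codes)]
}

#' Construct a barcode alignment
#'
#' An alignment is stored as a character matrix (samples x columns) of
#' uppercase IUPAC codes plus `-`. Column coordinates are 0-based half-open
#' internally; every user-facing report is 1-based.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return an object of class `barcode_aln`.
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sample ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  bad <- which(!(m %in% ALPHABET))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("illegal character '%s' in sample '%s' at position %d",
                 m[bad[1]], rownames(m)[i], j))
  }
  structure(m, class = "barcode_aln")
}

#' @export
print.barcode_aln <- function(x, ...) {
  cat(sprintf("barcode alignment: %d samples x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

aln_length <- function(aln) ncol(aln)

aln_strings <- function(aln, ids = rownames(aln)) {
  out <- apply(aln[ids, , drop = FALSE], 1, paste, collapse = "")
  names(out) <- ids
  out
}

#' Read a multi-FASTA alignment
#'
#' Sample ids are taken from the header up to the first whitespace; sequences
#' are uppercased. Ragged lengths, duplicate ids and characters outside the
#' IUPAC-plus-gap alphabet are errors.
#'
#' @param path path to an aligned FASTA file.
#' @return a [as_alignment()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("not a FASTA file (no '>' headers): ", path)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, "")
  seqs <- gsub("[[:space:]]", "", seqs)
  names(seqs) <- ids
  as_alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln a `barcode_aln`.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_alignment <- function(aln, path, width = 70) {
  seqs <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

SAMPLE_COLS <- c("sample_id", "species", "subspecies", "group", "locality",
                 "source")
GROUP_LEVELS <- c("target", "nontarget", "outgroup")

#' Read the sample-metadata table
#'
#' Tab-separated, one row per sample, with columns `sample_id`, `species`,
#' `subspecies`, `group` (target/nontarget/outgroup, case-insensitive),
#' `locality`, `source`.
#'
#' @param path TSV path.
#' @param aln optional alignment; if given, every aligned sample must have a
#'   metadata row.
#' @return a `data.frame` of class `sample_table`.
#' @export
read_metadata <- function(path, aln = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  as_sample_table(tab, aln)
}

#' Validate a sample table
#' @param tab data.frame with the metadata columns.
#' @param aln optional alignment to check coverage against.
#' @export
as_sample_table <- function(tab, aln = NULL) {
  missing_cols <- setdiff(SAMPLE_COLS, names(tab))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  tab$group <- tolower(tab$group)
  bad <- setdiff(unique(tab$group), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected target/nontarget/outgroup)")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in metadata")
  if (!is.null(aln)) {
    absent <- setdiff(rownames(aln), tab$sample_id)
    if (length(absent))
      stop("aligned samples missing from metadata: ",
           paste(absent, collapse = ", "))
  }
  class(tab) <- c("sample_table", "data.frame")
  tab
}

group_ids <- function(table, group) table$sample_id[table$group == group]

#' Trim an alignment to its overlapping core
#'
#' First removes columns whose non-gap fraction is below
#' `min_nongap_fraction`, then drops sequences covering (non-gap) less than
#' `min_span_fraction` of the remaining columns. The operation is idempotent.
#'
#' @param aln a `barcode_aln`.
#' @param min_nongap_fraction minimum fraction of non-gap calls for a column
#'   to be kept (default 0.7).
#' @param min_span_fraction minimum fraction of kept columns a sequence must
#'   cover (default 0.8).
#' @return the trimmed alignment, with attributes `removed_columns` (1-based)
#'   and `removed_samples`.
#' @export
trim_to_core <- function(aln, min_nongap_fraction = 0.7,
                         min_span_fraction = 0.8) {
  stopifnot(min_nongap_fraction > 0, min_nongap_fraction <= 1,
            min_span_fraction > 0, min_span_fraction <= 1)
  nongap <- colMeans(aln != "-")
  keep_col <- nongap >= min_nongap_fraction
  if (!any(keep_col)) stop("trimming removed every column")
  m <- unclass(aln)[, keep_col, drop = FALSE]
  span <- rowMeans(m != "-")
  keep_row <- span >= min_span_fraction
  if (!any(keep_row)) stop("trimming removed every sample")
  out <- structure(m[keep_row, , drop = FALSE], class = "barcode_aln")
  attr(out, "removed_columns") <- which(!keep_col)
  attr(out, "removed_samples") <- rownames(aln)[!keep_row]
  out
}

#' Collapse samples into haplotypes
#'
#' Exact string identity defines a haplotype; gaps and ambiguity codes are
#' ordinary characters and are never merged, so identity is reproducible and
#' order-independent.
#'
#' @param aln a `barcode_aln`.
#' @param ids subset of sample ids (default all).
#' @return object of class `haplotype_set`: list with `haplotypes` (named
#'   character vector, names H1..Hk in order of first appearance),
#'   `membership` (list of sample-id vectors), `counts`.
#' @export
collapse_haplotypes <- function(aln, ids = rownames(aln)) {
  if (!length(ids)) stop("empty id set")
  missing_ids <- setdiff(ids, rownames(aln))
  if (length(missing_ids))
    stop("ids not in alignment: ", paste(missing_ids, collapse = ", "))
  seqs <- aln_strings(aln, ids)
  uniq <- unique(unname(seqs))
  hap_names <- paste0("H", seq_along(uniq))
  membership <- lapply(uniq, function(s) names(seqs)[seqs == s])
  names(membership) <- hap_names
  haps <- stats::setNames(uniq, hap_names)
  structure(list(haplotypes = haps,
                 membership = membership,
                 counts = stats::setNames(lengths(membership), hap_names)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype set: %d haplotypes over %d samples\n",
              length(x$haplotypes), sum(x$counts)))
  invisible(x)
}

#' Consensus sequence of a sample subset
#'
#' Per column, the most frequent unambiguous base is called when it is unique
#' at the top and its frequency among unambiguous non-gap calls is at least
#' `plurality`; otherwise the minimal IUPAC code covering all bases at >= 25%
#' frequency is emitted (ties at the top always fall through to the IUPAC
#' rule). Ambiguity codes in the input do not enter the tally. An all-gap
#' column yields `-`.
#'
#' @param aln a `barcode_aln`.
#' @param ids subset of sample ids.
#' @param plurality minimum frequency for a plain base call (default 0.5).
#' @return a single consensus string.
#' @export
consensus_sequence <- function(aln, ids = rownames(aln), plurality = 0.5) {
  if (!length(ids)) stop("empty id set")
  m <- unclass(aln)[ids, , drop = FALSE]
  out <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    calls <- col[col %in% BASES]
    if (!length(calls)) {
      if (all(col == "-")) return("-")
      # only ambiguity codes present: cover their union
      sets <- unlist(IUPAC_SETS[col[col != "-"]])
      return(iupac_code_for(sets))
    }
    tab <- table(factor(calls, levels = BASES))
    freq <- as.numeric(tab) / length(calls)
    top <- which(freq == max(freq))
    if (length(top) == 1L && freq[top] >= plurality) return(BASES[top])
    covered <- BASES[freq >= 0.25]
    if (!length(covered)) covered <- BASES[top]
    iupac_code_for(covered)
  }, "")
  paste(out, collapse = "")
}

#' Classify variable alignment positions against group labels
#'
#' For each variable column the report records the states seen per group and
#' a classification: `fixed_difference` (every target carries a state no
#' nontarget carries), `autapomorphy` (a state unique to exactly one sample),
#' `shared_ancestral` (some but not all target samples retain the outgroup
#' state), or `variable_uninformative`. Columns where any compared sample
#' carries a gap or ambiguity code are classified but flagged low-confidence,
#' since degraded (e.g. museum-specimen) templates produce such calls.
#' Positions are 1-based.
#'
#' @param aln a `barcode_aln`.
#' @param table a `sample_table` covering the alignment.
#' @return data.frame with columns `position`, `classification`,
#'   `target_states`, `nontarget_states`, `outgroup_states`, `owner`
#'   (autapomorphy sample or NA), `low_confidence`.
#' @export
detect_diagnostic_sites <- function(aln, table) {
  table <- as_sample_table(table, aln)
  if (length(unique(table$group[table$sample_id %in% rownames(aln)])) < 2)
    stop("at least two groups are required")
  tgt <- intersect(group_ids(table, "target"), rownames(aln))
  non <- intersect(group_ids(table, "nontarget"), rownames(aln))
  out <- intersect(group_ids(table, "outgroup"), rownames(aln))
  m <- unclass(aln)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    uniq <- unique(col)
    if (length(uniq) < 2) return(NULL)
    ts <- unique(col[tgt]); ns <- unique(col[non]); os <- unique(col[out])
    lowconf <- any(!(col[c(tgt, non, out)] %in% BASES))
    cls <- "variable_uninformative"; owner <- NA_character_
    if (length(tgt) && length(non) &&
        length(ts) == 1L && !(ts %in% ns)) {
      cls <- "fixed_difference"
    } else {
      state_counts <- table(col)
      singles <- names(state_counts)[state_counts == 1L]
      apo <- singles[singles %in% BASES]
      if (length(apo) >= 1L) {
        cls <- "autapomorphy"
        owner <- names(col)[match(apo[1], col)]
        if (is.null(owner)) owner <- rownames(m)[match(apo[1], col)]
      } else if (length(os) == 1L && length(tgt) &&
                 any(col[tgt] == os) && !all(col[tgt] == os)) {
        cls <- "shared_ancestral"
      }
    }
    data.frame(position = j, classification = cls,
               target_states = paste(sort(ts), collapse = ","),
               nontarget_states = paste(sort(ns), collapse = ","),
               outgroup_states = paste(sort(os), collapse = ","),
               owner = owner, low_confidence = lowconf,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(position = integer(), classification = character(),
                      target_states = character(),
                      nontarget_states = character(),
                      outgroup_states = character(), owner = character(),
                      low_confidence = logical(), stringsAsFactors = FALSE)
  res
}

#' Fixed target/nontarget differences
#'
#' Convenience wrapper: 1-based positions where every target sample carries
#' one state and no nontarget sample carries it.
#' @inheritParams detect_diagnostic_sites
#' @return integer vector of positions.
#' @export
fixed_difference_positions <- function(aln, table) {
  rep_ <- detect_diagnostic_sites(aln, table)
  rep_$position[rep_$classification == "fixed_difference"]
}
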