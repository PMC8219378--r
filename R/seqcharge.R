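# Charged-residue census over a membrane-interface window of a Rho-family
# GTPase alignment, plus C-terminal tail lengths and a long/short tail
# classification. The window is given in the *ungapped* residue numbering
# of a reference sequence (e.g. the alpha-I helix window, residues 130-146
# of RhoD) and mapped onto alignment columns. Positive residues are K, R
# and H (histidine is counted positive: it is listed among the positively
# charged membrane-contacting residues in this system class); negative
# residues are D and E. The package consumes precomputed alignments and
# never builds one.

#' Read a multiple sequence alignment (aligned FASTA or Clustal)
#'
#' Sequences are case-normalized to upper case and `.` gap characters are
#' normalized to `-`. All gapped sequences must have equal length.
#'
#' @param path alignment file path.
#' @return object of class `Msa`: list with `ids` (unique sequence ids) and
#'   `seqs` (gapped residue strings, one per id).
#' @export
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop("alignment-format error: empty file")
  fmt <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
         else if (startsWith(first, ">")) "fasta"
         else stop("alignment-format error: neither FASTA nor Clustal: ", path)
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = fmt),
    error = function(e) {
      stop("alignment-format error (", fmt, "): ", conditionMessage(e),
           call. = FALSE)
    })
  seqs <- as.character(aln)
  ids <- names(seqs)
  # keep only the first token of FASTA headers
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("alignment-format error: duplicate sequence ids")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment-format error: gapped sequences have unequal lengths")
  }
  new_msa(ids, unname(seqs))
}

#' Construct an Msa from ids and gapped sequences
#' @param ids character vector of unique sequence ids.
#' @param seqs character vector of equal-length gapped residue strings.
#' @return an `Msa`.
#' @export
new_msa <- function(ids, seqs) {
  if (length(ids) != length(seqs)) stop("ids and seqs must have equal length")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  if (length(unique(nchar(seqs))) > 1L) {
    stop("alignment-format error: gapped sequences have unequal lengths")
  }
  structure(list(ids = as.character(ids), seqs = as.character(seqs)),
            class = "Msa")
}

#' @export
print.Msa <- function(x, ...) {
  cat(sprintf("Msa: %d sequences x %d columns\n", length(x$ids),
              nchar(x$seqs[1])))
  invisible(x)
}

msa_chars <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, ""))
}

# alignment column holding ungapped residue number `resno` of sequence row
ungapped_to_column <- function(seq_chars, resno) {
  nongap <- seq_chars != "-"
  cum <- cumsum(nongap)
  col <- match(resno, cum)
  if (is.na(col) || !nongap[col]) {
    stop(sprintf("residue number %d exceeds the reference's ungapped length (%d)",
                 resno, sum(nongap)))
  }
  col
}

#' Define an interface window in reference numbering
#'
#' @param ref_id id of the reference sequence in the alignment.
#' @param ranges list of inclusive `c(from, to)` residue-number ranges in
#'   the reference's ungapped numbering; must be non-overlapping.
#' @return object of class `InterfaceWindow`.
#' @export
interface_window <- function(ref_id, ranges) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  for (r in ranges) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
      stop("each range must be an inclusive c(from, to) with 1 <= from <= to")
    }
  }
  pos <- unlist(lapply(ranges, function(r) seq.int(r[1], r[2])))
  if (anyDuplicated(pos)) stop("window ranges overlap")
  structure(list(ref_id = ref_id, ranges = ranges), class = "InterfaceWindow")
}

#' Map an interface window onto alignment columns
#'
#' Converts the reference residue-number ranges to alignment columns and
#' returns every sequence's residues in those columns, gaps preserved.
#'
#' @param msa an `Msa`.
#' @param window an `InterfaceWindow`.
#' @return list with `columns` (integer alignment columns) and `residues`
#'   (named character vector: per-sequence window strings, possibly
#'   containing gaps).
#' @export
map_window <- function(msa, window) {
  stopifnot(inherits(msa, "Msa"), inherits(window, "InterfaceWindow"))
  row <- match(window$ref_id, msa$ids)
  if (is.na(row)) stop("reference id not found in alignment: ", window$ref_id)
  chars <- msa_chars(msa)
  refc <- chars[row, ]
  pos <- unlist(lapply(window$ranges, function(r) seq.int(r[1], r[2])))
  cols <- vapply(pos, function(p) ungapped_to_column(refc, p), integer(1))
  residues <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
  names(residues) <- msa$ids
  list(columns = cols, residues = residues)
}

#' Count charged residues in window strings
#'
#' `n_pos` counts K, R and H; `n_neg` counts D and E; gaps contribute
#' nothing. Any character other than the 20 amino acids, `X`, or the gap is
#' an error.
#'
#' @param residues character vector of (possibly gapped) window strings.
#' @return data.frame with columns `id` (names of the input, if any),
#'   `n_pos`, `n_neg`.
#' @export
charge_census <- function(residues) {
  aa_ok <- c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], "-")
  counts <- lapply(residues, function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- setdiff(ch, aa_ok)
    if (length(bad) > 0L) {
      stop("non-amino characters in window: ", paste(bad, collapse = ", "))
    }
    c(n_pos = sum(ch %in% c("K", "R", "H")),
      n_neg = sum(ch %in% c("D", "E")))
  })
  out <- as.data.frame(do.call(rbind, counts))
  out <- cbind(id = if (is.null(names(residues)))
    as.character(seq_along(residues)) else names(residues), out)
  rownames(out) <- NULL
  out
}

#' C-terminal tail length per sequence
#'
#' Locates the alignment column of the reference's catalytic-domain end
#' residue, then counts, for every sequence, the non-gap residues strictly
#' C-terminal to that column.
#'
#' @param msa an `Msa`.
#' @param ref_id reference sequence id.
#' @param ref_catalytic_end last residue of the catalytic domain, in the
#'   reference's ungapped numbering.
#' @return named integer vector of tail lengths (residues).
#' @export
tail_length <- function(msa, ref_id, ref_catalytic_end) {
  stopifnot(inherits(msa, "Msa"))
  row <- match(ref_id, msa$ids)
  if (is.na(row)) stop("reference id not found in alignment: ", ref_id)
  chars <- msa_chars(msa)
  col <- ungapped_to_column(chars[row, ], ref_catalytic_end)
  ncol_aln <- ncol(chars)
  if (col >= ncol_aln) {
    tails <- rep(0L, length(msa$ids))
  } else {
    after <- chars[, (col + 1L):ncol_aln, drop = FALSE]
    tails <- as.integer(rowSums(after != "-"))
  }
  names(tails) <- msa$ids
  tails
}

#' Charge/tail census table for a Rho-family alignment
#'
#' One record per retained sequence: positive and negative charged-residue
#' counts in the interface window, C-terminal tail length, and a
#' `long`/`short` tail class (`short` iff `tail_len <= tail_threshold`).
#' `tail_threshold` has no library default: the long/short boundary is a
#' reporting choice and must be stated by the caller.
#'
#' @param msa an `Msa`.
#' @param window an `InterfaceWindow`.
#' @param ref_catalytic_end catalytic-domain end residue (reference
#'   ungapped numbering).
#' @param tail_threshold tail length at or below which a tail is `short`.
#' @param exclude ids dropped from the census (default: the three family
#'   members carrying an extra domain C-terminal to the catalytic domain).
#' @return data.frame of `ChargeCensusRecord`s: columns `id`, `n_pos`,
#'   `n_neg`, `tail_len`, `tail_class`.
#' @export
census_table <- function(msa, window, ref_catalytic_end, tail_threshold,
                         exclude = c("RHBT1", "RHBT2", "RHBT3")) {
  if (missing(tail_threshold) || is.null(tail_threshold)) {
    stop("tail_threshold is required (no library default)")
  }
  win <- map_window(msa, window)
  cens <- charge_census(win$residues)
  tails <- tail_length(msa, window$ref_id, ref_catalytic_end)
  out <- data.frame(id = msa$ids, n_pos = cens$n_pos, n_neg = cens$n_neg,
                    tail_len = unname(tails),
                    stringsAsFactors = FALSE)
  out$tail_class <- ifelse(out$tail_len <= tail_threshold, "short", "long")
  out <- out[!(out$id %in% exclude), , drop = FALSE]
  rownames(out) <- NULL
  out
}
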